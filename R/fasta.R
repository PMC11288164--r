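#' Read a protein FASTA file into a record tibble
#'
#' One row per entry. The record id is the first whitespace-delimited token
#' of the header line; sequences are uppercased and validated against the
#' 20 standard amino acids plus `X`. Entry order is preserved.
#'
#' @param path Path to a FASTA file.
#' @param source_id Identifier of the genome or metagenome the proteins come
#'   from; defaults to the file name without extension.
#' @param source_kind `"genome"` or `"metagenome"`.
#' @return A tibble with columns `id`, `sequence`, `source_id`, `source_kind`.
#' @examples
#' f <- tempfile(fileext = ".faa")
#' writeLines(c(">g1 hypothetical", "MKV"), f)
#' read_fasta(f, source_id = "s1")
#' @export
read_fasta <- function(path, source_id = NULL,
                       source_kind = c("genome", "metagenome")) {
  source_kind <- match.arg(source_kind)
  if (!file.exists(path)) {
    abort(sprintf("FASTA file not found: %s", path))
  }
  source_id <- source_id %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  ids <- character()
  seqs <- character()
  chunks <- character()
  open <- FALSE
  flush <- function() {
    if (open) seqs[[length(seqs) + 1L]] <<- paste(chunks, collapse = "")
    chunks <<- character()
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (line == "") next
    if (startsWith(line, ">")) {
      flush()
      open <- TRUE
      id <- strsplit(sub("^>", "", line), "[[:space:]]+")[[1]][1]
      if (is.na(id) || id == "") {
        abort(sprintf("%s: malformed FASTA header at line %d", path, i))
      }
      ids[[length(ids) + 1L]] <- id
    } else {
      if (!open) {
        abort(sprintf("%s: sequence before any header at line %d", path, i))
      }
      line <- toupper(line)
      bad <- gsub(paste(AA_ALPHABET, collapse = "|"), "", line)
      if (nchar(bad) > 0) {
        abort(sprintf(
          "%s: illegal residue '%s' at line %d", path, substr(bad, 1, 1), i
        ))
      }
      chunks[[length(chunks) + 1L]] <- line
    }
  }
  flush()
  if (length(ids) > 0 && any(nchar(seqs) == 0)) {
    abort(sprintf(
      "%s: zero-length sequence for entry '%s'", path, ids[nchar(seqs) == 0][1]
    ))
  }
  if (anyDuplicated(ids)) {
    abort(sprintf(
      "%s: duplicate record id '%s'", path, ids[duplicated(ids)][1]
    ))
  }
  tibble(
    id = ids, sequence = seqs,
    source_id = rep(source_id, length(ids)),
    source_kind = rep(source_kind, length(ids))
  )
}

#' Write a record tibble to FASTA
#'
#' @param records Tibble with at least `id` and `sequence` columns.
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  records <- validate_records(records, require_source = FALSE)
  out <- character(0)
  if (nrow(records) > 0) {
    wrapped <- vapply(records$sequence, function(s) {
      starts <- seq(1L, nchar(s), by = width)
      paste(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
        collapse = "\n"
      )
    }, character(1))
    out <- as.vector(rbind(paste0(">", records$id), wrapped))
  }
  writeLines(out, path)
  invisible(path)
}

# Shared invariant checks for protein record tibbles.
validate_records <- function(records, require_source = TRUE) {
  records <- as_tibble(records)
  need <- c("id", "sequence", if (require_source) c("source_id", "source_kind"))
  missing <- setdiff(need, names(records))
  if (length(missing) > 0) {
    abort(paste0("record table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(records) == 0) {
    return(records)
  }
  if (any(grepl("[[:space:]]", records$id))) {
    abort("record ids must not contain whitespace")
  }
  records$sequence <- toupper(records$sequence)
  if (any(nchar(records$sequence) < 1)) {
    abort("sequences must have length >= 1")
  }
  ok <- grepl(sprintf("^[%s]+$", paste(AA_ALPHABET, collapse = "")), records$sequence)
  if (!all(ok)) {
    abort(sprintf("illegal residue in sequence for id '%s'", records$id[!ok][1]))
  }
  if (require_source && !all(records$source_kind %in% SOURCE_KINDS)) {
    abort("source_kind must be 'genome' or 'metagenome'")
  }
  records
}
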