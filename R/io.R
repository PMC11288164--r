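#' Read a sample metadata table
#'
#' Tab-separated with a header; expected columns `sample_id`, `source_kind`,
#' `body_site`, `oral_subsite`, `smoking`, `study`. Genome identifiers double
#' as sample identifiers for genome-type sources, so one table covers both
#' source kinds. Values outside the recognised category levels are mapped to
#' the explicit `"unknown"` level (or `"none"` for `oral_subsite`) rather
#' than dropped.
#'
#' @param path Path to the TSV file.
#' @return A tibble with the six metadata columns, levels normalised.
#' @export
read_metadata <- function(path) {
  md <- readr::read_tsv(path, show_col_types = FALSE)
  validate_metadata(md)
}

validate_metadata <- function(md) {
  md <- as_tibble(md)
  need <- c("sample_id", "source_kind", "body_site", "oral_subsite", "smoking")
  missing <- setdiff(need, names(md))
  if (length(missing) > 0) {
    abort(paste0("metadata lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (!"study" %in% names(md)) md$study <- "unknown"
  norm <- function(x, levels, fallback) {
    x <- as.character(x)
    x[is.na(x) | !(x %in% levels)] <- fallback
    x
  }
  md$source_kind <- as.character(md$source_kind)
  if (!all(md$source_kind %in% SOURCE_KINDS)) {
    abort("metadata source_kind must be 'genome' or 'metagenome'")
  }
  md$body_site <- norm(md$body_site, BODY_SITES, "unknown")
  md$oral_subsite <- norm(md$oral_subsite, ORAL_SUBSITES, "none")
  md$smoking <- norm(md$smoking, SMOKING_LEVELS, "unknown")
  bad <- md$oral_subsite != "none" & md$body_site != "oral"
  if (any(bad)) {
    abort(sprintf(
      "sample '%s' has an oral subsite but body_site '%s'",
      md$sample_id[bad][1], md$body_site[bad][1]
    ))
  }
  if (anyDuplicated(md$sample_id)) {
    abort("duplicate sample_id in metadata")
  }
  md[c("sample_id", "source_kind", "body_site", "oral_subsite", "smoking", "study")]
}

#' Read a taxonomy assignment table
#'
#' Tab-separated with a header; one row per genome with columns `genome_id`
#' plus any subset of the six GTDB ranks (`phylum`, `class`, `order`,
#' `family`, `genus`, `species`). Missing labels stay `NA` and are reported
#' as `"Unclassified"` by the summarisers.
#'
#' @param path Path to the TSV file.
#' @return A tibble with `genome_id` and the available rank columns.
#' @export
read_taxonomy <- function(path) {
  tx <- readr::read_tsv(path, show_col_types = FALSE)
  validate_taxonomy(tx)
}

validate_taxonomy <- function(tx) {
  tx <- as_tibble(tx)
  if (!"genome_id" %in% names(tx)) {
    abort("taxonomy table lacks a genome_id column")
  }
  extra <- setdiff(names(tx), c("genome_id", TAXONOMY_RANKS))
  if (length(extra) > 0) {
    abort(paste0(
      "taxonomy table has unrecognised rank column(s): ",
      paste(extra, collapse = ", ")
    ))
  }
  if (anyDuplicated(tx$genome_id)) {
    abort("duplicate genome_id in taxonomy table")
  }
  tx
}

#' Write an alignment hit table in tabular search format
#'
#' Columns follow the classic 15-column tabular protein-search layout
#' (`qseqid sseqid pident qcovhsp qlen slen length mismatch gapopen qstart
#' qend sstart send evalue bitscore`); the `evalue` column is a placeholder
#' (`NA`) since hits are gated on identity/coverage rather than E-value.
#'
#' @param hits Hit tibble as produced by [align_local()] / [find_candidates()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  out <- tibble(
    qseqid = hits$query_id, sseqid = hits$subject_id,
    pident = round(hits$identity_pct, 1), qcovhsp = round(hits$ref_coverage_pct, 1),
    qlen = hits$qlen, slen = hits$slen, length = hits$aln_len,
    mismatch = hits$mismatch, gapopen = hits$gapopen,
    qstart = hits$qstart, qend = hits$qend,
    sstart = hits$sstart, send = hits$send,
    evalue = NA_real_, bitscore = round(hits$bit_score, 1)
  )
  readr::write_tsv(out, path)
  invisible(path)
}
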