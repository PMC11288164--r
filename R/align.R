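#' Exact local alignment of two proteins
#'
#' Optimal Smith--Waterman alignment under affine gap penalties (a gap of
#' length L costs `gap_open + L * gap_extend`). One optimal local alignment
#' is reported; a pair whose optimal score is not strictly positive yields
#' no hit. The query is the reference side: `ref_coverage_pct` is the
#' fraction of the query spanned by the alignment, and `identity_pct` counts
#' identical residues over all alignment columns, gap columns included —
#' mirroring the `pident`/`qcovhsp` fields of tabular protein search output.
#'
#' @param query,subject One-row record tibbles (or lists) with `id` and
#'   `sequence`; the query is the reference.
#' @param scoring A [scoring_params()] object.
#' @return A hit tibble with columns `query_id`, `subject_id`, `raw_score`,
#'   `bit_score`, `identity_pct`, `ref_coverage_pct`, `qlen`, `slen`,
#'   `aln_len`, `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`, `send`;
#'   zero rows when there is no positive-scoring local alignment.
#' @examples
#' sc <- scoring_params()
#' align_local(list(id = "r", sequence = "MKVLITG"),
#'             list(id = "c", sequence = "MKVLITG"), sc)
#' @export
align_local <- function(query, subject, scoring = scoring_params()) {
  q <- as_record(query)
  s <- as_record(subject)
  hits_vs_reference(q, tibble(id = s$id, sequence = s$sequence), scoring)
}

as_record <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1)
    x <- as.list(x)
  }
  if (is.null(x$id) || is.null(x$sequence) || nchar(x$sequence) < 1) {
    abort("a record needs an id and a non-empty sequence")
  }
  x$sequence <- toupper(x$sequence)
  x
}

# All positive-scoring local hits of one reference (query) against a set of
# candidate proteins (subjects). Vectorised over the proteins.
hits_vs_reference <- function(ref, proteins, scoring) {
  stopifnot(inherits(scoring, "nde_scoring"))
  empty <- empty_hits()
  if (nrow(proteins) == 0) {
    return(empty)
  }
  pat <- Biostrings::AAStringSet(proteins$sequence)
  names(pat) <- proteins$id
  aln <- Biostrings::pairwiseAlignment(
    pattern = pat, subject = Biostrings::AAString(ref$sequence),
    substitutionMatrix = scoring$sub_matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
    type = "local"
  )
  raw <- Biostrings::score(aln)
  keep <- which(raw > 0)
  if (length(keep) == 0) {
    return(empty)
  }
  aln_len <- Biostrings::nchar(aln)[keep]
  nmatch <- Biostrings::nmatch(aln)[keep]
  nmm <- Biostrings::nmismatch(aln)[keep]
  pat_gapped <- as.character(Biostrings::alignedPattern(aln))[keep]
  sub_gapped <- as.character(Biostrings::alignedSubject(aln))[keep]
  gapopen <- count_gap_openings(pat_gapped) + count_gap_openings(sub_gapped)
  qstart <- Biostrings::start(Biostrings::subject(aln))[keep]
  qend <- Biostrings::end(Biostrings::subject(aln))[keep]
  sstart <- Biostrings::start(Biostrings::pattern(aln))[keep]
  send <- Biostrings::end(Biostrings::pattern(aln))[keep]
  qlen <- nchar(ref$sequence)
  tibble(
    query_id = ref$id,
    subject_id = proteins$id[keep],
    raw_score = as.numeric(raw[keep]),
    bit_score = bit_score(raw[keep], scoring),
    identity_pct = 100 * nmatch / aln_len,
    ref_coverage_pct = 100 * (qend - qstart + 1) / qlen,
    qlen = qlen,
    slen = nchar(proteins$sequence)[keep],
    aln_len = aln_len,
    mismatch = nmm,
    gapopen = gapopen,
    qstart = qstart, qend = qend, sstart = sstart, send = send
  )
}

count_gap_openings <- function(gapped) {
  vapply(gapped, function(s) {
    r <- rle(strsplit(s, "")[[1]] == "-")
    sum(r$values)
  }, integer(1), USE.NAMES = FALSE)
}

empty_hits <- function() {
  tibble(
    query_id = character(), subject_id = character(),
    raw_score = numeric(), bit_score = numeric(),
    identity_pct = numeric(), ref_coverage_pct = numeric(),
    qlen = integer(), slen = integer(), aln_len = integer(),
    mismatch = integer(), gapopen = integer(),
    qstart = integer(), qend = integer(), sstart = integer(), send = integer()
  )
}

# Best raw score of `record` against each sequence in `others`; used by the
# ScoreRef/ScoreOut stage where only the maximum matters.
best_raw_score <- function(record, others, scoring) {
  if (nrow(others) == 0) {
    return(NA_real_)
  }
  pat <- Biostrings::AAStringSet(others$sequence)
  raw <- Biostrings::pairwiseAlignment(
    pattern = pat, subject = Biostrings::AAString(record$sequence),
    substitutionMatrix = scoring$sub_matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
    type = "local", scoreOnly = TRUE
  )
  max(raw)
}
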