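#' ScoreRef and ScoreOut for candidate proteins
#'
#' Re-searches each candidate against the full reference panel and the
#' outgroup panel: `score_ref` is the highest bit score against any
#' reference, `score_out` the highest against any outgroup (`NA` when the
#' family has no outgroups, as for NicA2).
#'
#' @param candidates Candidate tibble from [find_candidates()] (needs
#'   `protein_id` and `sequence`).
#' @param panel `nde_panels` tibble for the candidates' family.
#' @param scoring A [scoring_params()] object.
#' @return `candidates` with numeric columns `score_ref` and `score_out`.
#' @export
compute_ref_out_scores <- function(candidates, panel, scoring = scoring_params()) {
  candidates <- as_tibble(candidates)
  refs <- panel_refs(panel)
  outs <- panel_outs(panel)
  score_pair <- function(sequence, id) {
    rec <- list(id = id, sequence = sequence)
    raw_ref <- best_raw_score(rec, refs, scoring)
    if (is.na(raw_ref) || raw_ref <= 0) {
      abort(sprintf(
        "protein '%s' has no positive-scoring reference alignment; it cannot be a candidate",
        id
      ))
    }
    raw_out <- best_raw_score(rec, outs, scoring)
    c(
      ref = bit_score(raw_ref, scoring),
      out = if (is.na(raw_out) || raw_out <= 0) NA_real_ else bit_score(raw_out, scoring)
    )
  }
  sc <- purrr::map2(candidates$sequence, candidates$protein_id, score_pair)
  candidates$score_ref <- purrr::map_dbl(sc, "ref")
  candidates$score_out <- purrr::map_dbl(sc, "out")
  candidates
}

#' Outgroup score-ratio rule
#'
#' A candidate is excluded when its best reference bit score is strictly
#' less than `ratio` times its best outgroup bit score
#' (`score_ref < ratio * score_out`); equality keeps the candidate, and a
#' candidate with no outgroup score (family without outgroups, or no
#' positive-scoring outgroup alignment) is kept. Vectorised.
#'
#' @param score_ref,score_out Bit scores; `score_out` may be `NA`.
#' @param ratio Ratio threshold, >= 1 (default 1.2).
#' @return Logical vector: `TRUE` = keep.
#' @examples
#' score_ratio_decision(60, 50)   # kept: 60 == 1.2 * 50
#' score_ratio_decision(59.9, 50) # excluded
#' @export
score_ratio_decision <- function(score_ref, score_out, ratio = 1.2) {
  if (ratio < 1) {
    abort("ratio must be >= 1")
  }
  if (any(score_ref <= 0, na.rm = TRUE)) {
    abort("score_ref must be positive")
  }
  ifelse(is.na(score_out), TRUE, !(score_ref < ratio * score_out))
}

#' Screen a candidate for overlong insertions or deletions
#'
#' End-gap-free global alignment of the candidate against its best
#' reference; over the aligned core (terminal overhangs ignored) the longest
#' contiguous gap run in the reference row (an insertion in the candidate)
#' and in the candidate row (a deletion) are measured. The candidate is
#' excluded when either run exceeds `max_indel_run`. This automates the
#' manual alignment-inspection step that removes sequences with too long
#' insertions or deletions.
#'
#' @param candidate,reference One-row record tibbles or lists with `id` and
#'   `sequence`.
#' @param scoring A [scoring_params()] object.
#' @param max_indel_run Longest tolerated run, in residues.
#' @return One-row tibble: `protein_id`, `max_insertion_run`,
#'   `max_deletion_run`, `indel_passed`.
#' @export
indel_inspection <- function(candidate, reference, scoring = scoring_params(),
                             max_indel_run = 50L) {
  cand <- as_record(candidate)
  ref <- as_record(reference)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(cand$sequence),
    subject = Biostrings::AAString(ref$sequence),
    substitutionMatrix = scoring$sub_matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
    type = "overlap"
  )
  cand_row <- as.character(Biostrings::alignedPattern(aln))
  ref_row <- as.character(Biostrings::alignedSubject(aln))
  ins_run <- longest_gap_run(ref_row)
  del_run <- longest_gap_run(cand_row)
  tibble(
    protein_id = cand$id,
    max_insertion_run = ins_run,
    max_deletion_run = del_run,
    indel_passed = ins_run <= max_indel_run && del_run <= max_indel_run
  )
}

longest_gap_run <- function(gapped) {
  chars <- strsplit(gapped, "")[[1]]
  # trim terminal overhang gaps: only the aligned core counts
  core <- which(chars != "-")
  if (length(core) == 0) {
    return(0L)
  }
  chars <- chars[seq(min(core), max(core))]
  r <- rle(chars == "-")
  runs <- r$lengths[r$values]
  if (length(runs) == 0) 0L else as.integer(max(runs))
}
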