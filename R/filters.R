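#' Candidate filtering parameters
#'
#' Thresholds for the annotation cascade. The gate values follow the
#' pipeline's exclusion rules: hits with reference coverage below 40% or
#' identity below 30% are excluded, as are candidate proteins shorter than
#' 50% or longer than 150% of the reference length. Because every exclusion
#' is a strict inequality, boundary values (exactly 30%, 40%, 50%, 150%) are
#' kept. `score_ratio` is the outgroup rule (exclude when
#' `score_ref < score_ratio * score_out`); `tree_margin` operationalises the
#' "distance to reference close to or bigger than distance to outgroup"
#' exclusion as keep iff `d_ref < tree_margin * d_out`; `max_indel_run` caps
#' the longest contiguous insertion or deletion tolerated against the best
#' reference.
#'
#' @param min_ref_coverage_pct,min_identity_pct Gate minima in percent.
#' @param min_len_frac,max_len_frac Candidate length window relative to the
#'   reference length.
#' @param score_ratio Outgroup bit-score ratio; must be >= 1.
#' @param tree_margin Patristic-distance margin in (0, 1].
#' @param max_indel_run Longest tolerated gap run, in residues.
#' @return An object of class `nde_filters`.
#' @export
filter_params <- function(min_ref_coverage_pct = 40, min_identity_pct = 30,
                          min_len_frac = 0.5, max_len_frac = 1.5,
                          score_ratio = 1.2, tree_margin = 0.9,
                          max_indel_run = 50L) {
  if (min_len_frac <= 0 || min_len_frac >= max_len_frac) {
    abort("length fractions must satisfy 0 < min_len_frac < max_len_frac")
  }
  if (score_ratio < 1) {
    abort("score_ratio must be >= 1")
  }
  if (tree_margin <= 0 || tree_margin > 1) {
    abort("tree_margin must lie in (0, 1]")
  }
  if (min_ref_coverage_pct <= 0 || min_identity_pct <= 0 || max_indel_run <= 0) {
    abort("all thresholds must be positive")
  }
  structure(
    list(
      min_ref_coverage_pct = min_ref_coverage_pct,
      min_identity_pct = min_identity_pct,
      min_len_frac = min_len_frac, max_len_frac = max_len_frac,
      score_ratio = score_ratio, tree_margin = tree_margin,
      max_indel_run = as.integer(max_indel_run)
    ),
    class = "nde_filters"
  )
}

#' Apply the coverage/identity/length gates to alignment hits
#'
#' A hit passes when `ref_coverage_pct >= min_ref_coverage_pct`,
#' `identity_pct >= min_identity_pct`, and the full candidate length lies in
#' `[min_len_frac, max_len_frac]` times the full reference length (bounds
#' inclusive — the underlying exclusions are strict inequalities).
#'
#' @param hits Hit tibble from [align_local()].
#' @param filters A [filter_params()] object.
#' @return `hits` with logical `passed` and list-column `failed_rules`
#'   (character vector drawn from `"coverage"`, `"identity"`, `"length"`).
#' @export
hit_passes_thresholds <- function(hits, filters = filter_params()) {
  stopifnot(inherits(filters, "nde_filters"))
  hits <- as_tibble(hits)
  fail_cov <- hits$ref_coverage_pct < filters$min_ref_coverage_pct
  fail_id <- hits$identity_pct < filters$min_identity_pct
  fail_len <- hits$slen < filters$min_len_frac * hits$qlen |
    hits$slen > filters$max_len_frac * hits$qlen
  hits$passed <- !(fail_cov | fail_id | fail_len)
  hits$failed_rules <- purrr::pmap(
    list(fail_cov, fail_id, fail_len),
    function(cv, id, ln) {
      c(if (cv) "coverage", if (id) "identity", if (ln) "length")
    }
  )
  hits
}

#' Search a proteome for candidate NDEs of one family
#'
#' Aligns every reference of the panel against every protein and keeps, per
#' protein, those with at least one gate-passing hit. Each such protein
#' becomes exactly one candidate, carrying its best reference hit (highest
#' bit score; ties broken by higher identity, then lexicographic reference
#' id). The result is independent of the input order of the proteome.
#'
#' @param proteome Record tibble of proteins from one or more sources.
#' @param panel An `nde_panels` tibble restricted to one NDE family (extra
#'   families are an error).
#' @param scoring A [scoring_params()] object.
#' @param filters A [filter_params()] object.
#' @param keep_failed Also return, with `passed = FALSE`, proteins whose best
#'   hit exists but fails the gates (used for the per-stage decision trail).
#' @return A candidate tibble: `protein_id`, `source_id`, `source_kind`,
#'   `sequence`, `nde_type`, the best-hit columns, `passed`, `failed_rules`.
#' @export
find_candidates <- function(proteome, panel, scoring = scoring_params(),
                            filters = filter_params(), keep_failed = FALSE) {
  proteome <- validate_records(proteome)
  panel <- as_tibble(panel)
  type <- unique(panel$nde_type)
  if (length(type) != 1) {
    abort("find_candidates expects a panel for exactly one nde_type")
  }
  refs <- panel_refs(panel)
  if (nrow(proteome) == 0) {
    return(empty_candidates())
  }
  if (anyDuplicated(paste(proteome$source_id, proteome$id))) {
    abort("duplicate protein id within a source")
  }
  hits <- purrr::map(seq_len(nrow(refs)), function(i) {
    hits_vs_reference(as.list(refs[i, ]), proteome, scoring)
  }) |>
    bind_rows() |>
    hit_passes_thresholds(filters)
  if (nrow(hits) == 0) {
    return(empty_candidates())
  }
  best <- hits |>
    arrange(
      .data$subject_id, dplyr::desc(.data$passed), dplyr::desc(.data$bit_score),
      dplyr::desc(.data$identity_pct), .data$query_id
    ) |>
    group_by(.data$subject_id) |>
    dplyr::slice_head(n = 1) |>
    ungroup()
  if (!keep_failed) {
    best <- filter(best, .data$passed)
  }
  out <- best |>
    left_join(
      proteome |> select(subject_id = "id", "source_id", "source_kind", "sequence"),
      by = "subject_id"
    ) |>
    mutate(nde_type = type) |>
    rename(protein_id = "subject_id") |>
    select(
      "protein_id", "source_id", "source_kind", "sequence", "nde_type",
      "query_id", "raw_score", "bit_score", "identity_pct", "ref_coverage_pct",
      "qlen", "slen", "aln_len", "mismatch", "gapopen",
      "qstart", "qend", "sstart", "send", "passed", "failed_rules"
    ) |>
    arrange(.data$source_id, .data$protein_id)
  out
}

empty_candidates <- function() {
  tibble(
    protein_id = character(), source_id = character(), source_kind = character(),
    sequence = character(), nde_type = character(),
    query_id = character(), raw_score = numeric(), bit_score = numeric(),
    identity_pct = numeric(), ref_coverage_pct = numeric(),
    qlen = integer(), slen = integer(), aln_len = integer(),
    mismatch = integer(), gapopen = integer(),
    qstart = integer(), qend = integer(), sstart = integer(), send = integer(),
    passed = logical(), failed_rules = list()
  )
}
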