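#' Phylogenetic-distance discrimination filter
#'
#' Builds one neighbor-joining tree per NDE family containing the surviving
#' candidates plus the family's reference and outgroup sequences (Kimura
#' distances, see [protein_distance_matrix()]), then compares each
#' candidate's patristic distance to its closest reference leaf (`d_ref`)
#' with that to its closest outgroup leaf (`d_out`). A candidate whose
#' reference distance is close to or bigger than its outgroup distance is
#' excluded: keep iff `d_ref < tree_margin * d_out`, so equality is always
#' excluded. Families without outgroups bypass the filter (all kept,
#' `d_out = NA`), as does a tree with fewer than three leaves (with a
#' warning).
#'
#' @param candidates Candidate tibble (one family) with `protein_id`,
#'   `source_id`, `sequence`.
#' @param panel `nde_panels` tibble for that family.
#' @param filters A [filter_params()] object (supplies `tree_margin`).
#' @param scoring A [scoring_params()] object.
#' @return A tibble with `protein_id`, `source_id`, `d_ref`, `d_out`,
#'   `tree_passed`; the `phylo` tree (or `NULL`) is attached as attribute
#'   `"tree"`, with candidate tips labelled `cand::<source>::<protein>`,
#'   references `ref::<id>`, outgroups `out::<id>`.
#' @export
tree_filter <- function(candidates, panel, filters = filter_params(),
                        scoring = scoring_params()) {
  candidates <- as_tibble(candidates)
  refs <- panel_refs(panel)
  outs <- panel_outs(panel)
  result <- tibble(
    protein_id = candidates$protein_id,
    source_id = candidates$source_id,
    d_ref = NA_real_, d_out = NA_real_,
    tree_passed = TRUE
  )
  if (nrow(candidates) == 0 || nrow(outs) == 0) {
    attr(result, "tree") <- NULL
    return(result)
  }
  leaves <- bind_rows(
    tibble(
      id = paste0("cand::", candidates$source_id, "::", candidates$protein_id),
      sequence = candidates$sequence
    ),
    tibble(id = paste0("ref::", refs$id), sequence = refs$sequence),
    tibble(id = paste0("out::", outs$id), sequence = outs$sequence)
  )
  if (nrow(leaves) < 3) {
    warn("fewer than 3 leaves; tree filter skipped, all candidates kept")
    attr(result, "tree") <- NULL
    return(result)
  }
  dm <- protein_distance_matrix(leaves, scoring)
  tree <- nj_tree(dm)
  pm <- ape::cophenetic.phylo(tree)
  ref_tips <- paste0("ref::", refs$id)
  out_tips <- paste0("out::", outs$id)
  cand_tips <- leaves$id[seq_len(nrow(candidates))]
  result$d_ref <- unname(apply(pm[cand_tips, ref_tips, drop = FALSE], 1, min))
  result$d_out <- unname(apply(pm[cand_tips, out_tips, drop = FALSE], 1, min))
  result$tree_passed <- result$d_ref < filters$tree_margin * result$d_out
  attr(result, "tree") <- tree
  result
}
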