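#' Annotate NDE homologs with the full filter cascade
#'
#' Runs, for every family in `panels`, the complete annotation pipeline over
#' a protein catalog: candidate search with the identity/coverage/length
#' gates ([find_candidates()]), the outgroup score-ratio rule
#' ([score_ratio_decision()]), the long-indel screen ([indel_inspection()]),
#' and the phylogenetic-distance filter ([tree_filter()]). Every protein
#' with at least one positive-scoring reference hit appears in the output
#' with its per-stage decision trail; `final_status` is `"annotated"` only
#' for candidates that pass every stage applied to their family. Families
#' without outgroups (NicA2) bypass the two outgroup stages and are
#' annotated on the gates and indel screen alone.
#'
#' @param proteomes Record tibble of all proteins across sources (columns
#'   `id`, `sequence`, `source_id`, `source_kind`).
#' @param panels `nde_panels` tibble covering one or more families.
#' @param scoring A [scoring_params()] object.
#' @param filters A [filter_params()] object.
#' @return An object of class `nde_annotation`: a list with
#'   * `annotations` — one row per (protein, family) with hit metrics,
#'     `score_ref`/`score_out`, indel runs, `d_ref`/`d_out`, per-stage
#'     `*_passed` flags, a `decisions` list-column, `failed_stage`, and
#'     `final_status` (`"annotated"` / `"excluded"`);
#'   * `trees` — named list of `phylo` discrimination trees per family;
#'   * `stage_log` — per family and stage, candidates entered/kept/excluded;
#'   * `scoring`, `filters` — the parameters used.
#' Use [tidy()] for the annotation tibble, [glance()] for per-family counts,
#' and [autoplot()] for the count figure.
#' @export
annotate_nde <- function(proteomes, panels, scoring = scoring_params(),
                         filters = filter_params()) {
  proteomes <- validate_records(proteomes)
  panels <- as_tibble(panels)
  types <- unique(panels$nde_type)
  per_type <- purrr::map(types, function(type) {
    annotate_one_type(proteomes, panel_for_type(panels, type), scoring, filters)
  })
  annotations <- bind_rows(purrr::map(per_type, "annotations")) |>
    arrange(.data$nde_type, .data$source_id, .data$protein_id)
  trees <- purrr::compact(setNames(purrr::map(per_type, "tree"), types))
  stage_log <- bind_rows(purrr::map(per_type, "stage_log"))
  structure(
    list(
      annotations = annotations, trees = trees, stage_log = stage_log,
      scoring = scoring, filters = filters
    ),
    class = "nde_annotation"
  )
}

annotate_one_type <- function(proteomes, panel, scoring, filters) {
  type <- unique(panel$nde_type)
  refs <- panel_refs(panel)
  has_outgroup <- nrow(panel_outs(panel)) > 0
  cands <- find_candidates(proteomes, panel, scoring, filters, keep_failed = TRUE)
  cands$thresholds_passed <- cands$passed
  cands$score_ref <- NA_real_
  cands$score_out <- NA_real_
  cands$ratio_passed <- NA
  cands$max_insertion_run <- NA_integer_
  cands$max_deletion_run <- NA_integer_
  cands$indel_passed <- NA
  cands$d_ref <- NA_real_
  cands$d_out <- NA_real_
  cands$tree_passed <- NA
  tree <- NULL

  log <- list(stage_row(type, "thresholds", nrow(cands), sum(cands$thresholds_passed)))
  alive <- which(cands$thresholds_passed)

  # Outgroup score-ratio rule (bypassed, all kept, when no outgroups exist)
  if (length(alive) > 0) {
    scored <- compute_ref_out_scores(cands[alive, ], panel, scoring)
    cands$score_ref[alive] <- scored$score_ref
    cands$score_out[alive] <- scored$score_out
    cands$ratio_passed[alive] <- score_ratio_decision(
      scored$score_ref, scored$score_out, filters$score_ratio
    )
  }
  log <- c(log, list(stage_row(
    type, "score_ratio", length(alive), sum(cands$ratio_passed[alive])
  )))
  alive <- which(cands$thresholds_passed & cands$ratio_passed %in% TRUE)

  # Long-indel screen against each candidate's best reference
  if (length(alive) > 0) {
    runs <- purrr::map(alive, function(i) {
      ref <- refs[refs$id == cands$query_id[i], ]
      indel_inspection(
        list(id = cands$protein_id[i], sequence = cands$sequence[i]),
        as.list(ref[1, ]), scoring, filters$max_indel_run
      )
    }) |> bind_rows()
    cands$max_insertion_run[alive] <- runs$max_insertion_run
    cands$max_deletion_run[alive] <- runs$max_deletion_run
    cands$indel_passed[alive] <- runs$indel_passed
  }
  log <- c(log, list(stage_row(
    type, "indel_inspection", length(alive), sum(cands$indel_passed[alive])
  )))
  alive <- which(cands$thresholds_passed & cands$ratio_passed %in% TRUE &
    cands$indel_passed %in% TRUE)

  # Phylogenetic-distance filter (bypassed when no outgroups exist)
  if (length(alive) > 0 && has_outgroup) {
    tf <- tree_filter(cands[alive, ], panel, filters, scoring)
    cands$d_ref[alive] <- tf$d_ref
    cands$d_out[alive] <- tf$d_out
    cands$tree_passed[alive] <- tf$tree_passed
    tree <- attr(tf, "tree")
  } else if (length(alive) > 0) {
    cands$tree_passed[alive] <- TRUE
  }
  log <- c(log, list(stage_row(
    type, "tree_filter", length(alive), sum(cands$tree_passed[alive])
  )))

  cands$final_status <- ifelse(
    cands$thresholds_passed & cands$ratio_passed %in% TRUE &
      cands$indel_passed %in% TRUE & cands$tree_passed %in% TRUE,
    "annotated", "excluded"
  )
  cands$failed_stage <- dplyr::case_when(
    !cands$thresholds_passed ~ "thresholds",
    !cands$ratio_passed ~ "score_ratio",
    !cands$indel_passed ~ "indel_inspection",
    !cands$tree_passed ~ "tree_filter",
    TRUE ~ NA_character_
  )
  cands$decisions <- purrr::pmap(
    cands[c("thresholds_passed", "ratio_passed", "indel_passed", "tree_passed")],
    function(thresholds_passed, ratio_passed, indel_passed, tree_passed) {
      trace <- tibble(
        stage = c("thresholds", "score_ratio", "indel_inspection", "tree_filter"),
        passed = c(thresholds_passed, ratio_passed, indel_passed, tree_passed)
      )
      filter(trace, !is.na(.data$passed))
    }
  )
  list(
    annotations = select(cands, -"passed", -"failed_rules"),
    tree = tree,
    stage_log = bind_rows(log)
  )
}

stage_row <- function(type, stage, entered, kept) {
  kept <- if (entered == 0) 0L else as.integer(kept)
  tibble(
    nde_type = type, stage = stage,
    entered = as.integer(entered), kept = kept,
    excluded = as.integer(entered) - kept
  )
}

#' @export
print.nde_annotation <- function(x, ...) {
  ann <- x$annotations
  cat("<nde_annotation>\n")
  cat(sprintf(
    "  %d screened proteins (%d passed gates), %d annotated, %d sources, %d famil%s\n",
    nrow(ann), sum(ann$thresholds_passed), sum(ann$final_status == "annotated"),
    dplyr::n_distinct(ann$source_id), length(unique(ann$nde_type)),
    if (length(unique(ann$nde_type)) == 1) "y" else "ies"
  ))
  invisible(x)
}

#' @rdname annotate_nde
#' @param x An `nde_annotation` object.
#' @param ... Unused.
#' @export
tidy.nde_annotation <- function(x, ...) {
  x$annotations
}

#' @rdname annotate_nde
#' @export
glance.nde_annotation <- function(x, ...) {
  x$annotations |>
    group_by(.data$nde_type) |>
    summarise(
      n_candidates = sum(.data$thresholds_passed),
      n_annotated = sum(.data$final_status == "annotated"),
      n_positive_sources = dplyr::n_distinct(
        .data$source_id[.data$final_status == "annotated"]
      ),
      .groups = "drop"
    )
}
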