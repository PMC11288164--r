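#' Build a ground-truth benchmark data set
#'
#' Generates, deterministically from the configuration seed, a reference
#' panel, per-sample protein catalogs with planted sequences, sample
#' metadata, a taxonomy table for genome sources, and a truth table stating
#' for every planted sequence which class it belongs to and at which
#' pipeline stage it should be resolved:
#' * `true_homolog` — reference-clade descendant; should be `annotated`;
#' * `decoy_outgroup` — outgroup-clade descendant; similar enough to pass
#'   the gates, must be caught by the `score_ratio` or `tree_filter` stage;
#' * `decoy_random` — i.i.d.-residue protein; caught at `thresholds`
#'   (typically no qualifying hit at all);
#' * `decoy_length` — truncated or extended homolog; caught at `thresholds`
#'   by the coverage/length gates.
#'
#' Positive samples per layout row are fixed by largest-remainder rounding
#' of `n * prevalence`; each positive sample receives one true homolog, and
#' any configured surplus homologs go to already-positive samples so group
#' prevalences are unchanged. Every sample also receives `n_background`
#' unplanted random proteins.
#'
#' @param config A [simulation_config()] object.
#' @return A list: `panels` (`nde_panels`), `proteomes` (record tibble),
#'   `metadata`, `taxonomy`, `truth` tibbles, and `config`.
#' @export
build_benchmark <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, build_benchmark_impl(config))
}

build_benchmark_impl <- function(config) {
  scoring <- scoring_params()
  founder_ref <- random_protein(config$ancestor_length, "founder_ref")
  founder_out <- evolve_protein(
    founder_ref, config$ref_out_identity, config$indel_rate,
    id = "founder_out", scoring = scoring
  )
  evolve_set <- function(founder, n, identity, prefix) {
    purrr::map(seq_len(n), function(i) {
      evolve_protein(founder, identity, config$indel_rate,
        id = sprintf("%s%d", prefix, i), scoring = scoring
      )
    })
  }
  refs <- evolve_set(
    founder_ref, config$n_references, config$ref_clade_divergence, "REF"
  )
  outs <- evolve_set(
    founder_out, config$n_outgroups, config$out_clade_divergence, "OUT"
  )
  to_tbl <- function(recs) {
    tibble(
      id = purrr::map_chr(recs, "id"),
      sequence = purrr::map_chr(recs, "sequence")
    )
  }
  panels <- reference_panel(
    to_tbl(refs), config$nde_type,
    outgroups = if (config$n_outgroups > 0) to_tbl(outs) else NULL
  )

  layout <- config$per_sample_layout
  metadata <- layout |>
    mutate(.row = row_number()) |>
    tidyr::uncount(.data$n, .remove = FALSE) |>
    group_by(.data$.row) |>
    mutate(.k = row_number()) |>
    ungroup() |>
    mutate(
      sample_id = sprintf(
        "%s%03d", ifelse(.data$source_kind == "genome", "G", "S"), row_number()
      )
    )
  positives_per_row <- allocate_positives(layout$n, layout$prevalence)
  metadata$positive_planted <- unlist(purrr::map2(
    layout$n, positives_per_row,
    function(n, k) c(rep(TRUE, k), rep(FALSE, n - k))
  ))
  positive_ids <- metadata$sample_id[metadata$positive_planted]
  n_hom <- config$n_true_homologs %||% length(positive_ids)
  if (n_hom < length(positive_ids)) {
    abort(sprintf(
      "n_true_homologs (%d) is smaller than the %d prevalence-positive samples",
      n_hom, length(positive_ids)
    ))
  }
  if (n_hom > 0 && length(positive_ids) == 0) {
    abort("n_true_homologs > 0 but the layout plants no positive samples")
  }
  hom_samples <- c(
    positive_ids,
    if (n_hom > length(positive_ids)) {
      sample(positive_ids, n_hom - length(positive_ids), replace = TRUE)
    }
  )

  plant <- function(n, prefix, class, make) {
    purrr::map(seq_len(n), function(i) {
      rec <- make(i, sprintf("%s_%03d", prefix, i))
      c(rec, list(class = class))
    })
  }
  homologs <- plant(
    length(hom_samples), "HOM", "true_homolog",
    function(i, id) {
      parent <- refs[[sample(config$n_references, 1)]]
      t <- stats::runif(
        1, config$homolog_identity_range[1], config$homolog_identity_range[2]
      )
      rec <- evolve_protein(parent, t, config$indel_rate, id = id, scoring = scoring)
      c(rec, list(target_identity = t, sample_id = hom_samples[i]))
    }
  )
  all_samples <- metadata$sample_id
  round_robin <- function(i) all_samples[(i - 1) %% length(all_samples) + 1]
  dec_out <- plant(
    config$n_decoys_outgroup_side, "DECOUT", "decoy_outgroup",
    function(i, id) {
      parent <- outs[[sample(max(config$n_outgroups, 1), 1)]]
      t <- stats::runif(
        1, config$decoy_identity_range[1], config$decoy_identity_range[2]
      )
      rec <- evolve_protein(parent, t, config$indel_rate, id = id, scoring = scoring)
      c(rec, list(target_identity = t, sample_id = round_robin(i)))
    }
  )
  dec_rnd <- plant(
    config$n_decoys_random, "DECRND", "decoy_random",
    function(i, id) {
      len <- round(config$ancestor_length * stats::runif(1, 0.6, 1.4))
      rec <- random_protein(len, id)
      c(rec, list(target_identity = NA_real_, sample_id = round_robin(i)))
    }
  )
  dec_len <- plant(
    config$n_decoys_length, "DECLEN", "decoy_length",
    function(i, id) {
      parent <- refs[[sample(config$n_references, 1)]]
      rec <- evolve_protein(parent, 0.8, config$indel_rate, id = id, scoring = scoring)
      chars <- strsplit(rec$sequence, "")[[1]]
      len <- length(chars)
      if (i %% 2 == 1) {
        # truncated variant: well under 50% of the reference length
        keep <- round(0.35 * len)
        at <- sample(len - keep + 1, 1)
        rec$sequence <- paste(chars[at:(at + keep - 1)], collapse = "")
      } else {
        # extended variant: pad beyond 150% of the reference length
        pad <- sample(AA_STANDARD, round(0.7 * len), replace = TRUE)
        rec$sequence <- paste(c(chars, pad), collapse = "")
      }
      c(rec, list(target_identity = 0.8, sample_id = round_robin(i)))
    }
  )
  planted <- c(homologs, dec_out, dec_rnd, dec_len)
  background <- purrr::map(all_samples, function(s) {
    purrr::map(seq_len(config$n_background), function(i) {
      len <- round(config$ancestor_length * stats::runif(1, 0.5, 1.2))
      rec <- random_protein(len, sprintf("BG_%s_%02d", s, i))
      c(rec, list(class = "background", target_identity = NA_real_, sample_id = s))
    })
  }) |> purrr::flatten()

  all_prot <- c(planted, background)
  kind_of <- setNames(metadata$source_kind, metadata$sample_id)
  proteomes <- tibble(
    id = purrr::map_chr(all_prot, "id"),
    sequence = purrr::map_chr(all_prot, "sequence"),
    source_id = purrr::map_chr(all_prot, "sample_id"),
    source_kind = unname(kind_of[purrr::map_chr(all_prot, "sample_id")])
  )
  truth <- tibble(
    protein_id = purrr::map_chr(planted, "id"),
    source_id = purrr::map_chr(planted, "sample_id"),
    class = purrr::map_chr(planted, "class"),
    target_identity = purrr::map_dbl(planted, "target_identity"),
    nde_type = config$nde_type
  ) |>
    mutate(expected_stage = dplyr::case_when(
      .data$class == "true_homolog" ~ "annotated",
      .data$class == "decoy_outgroup" ~ "outgroup_filter",
      TRUE ~ "thresholds"
    ))

  genome_ids <- metadata$sample_id[metadata$source_kind == "genome"]
  taxonomy <- NULL
  if (length(genome_ids) > 0) {
    phyla <- sample(
      c("Proteobacteria", "Firmicutes", "Bacteroidota"),
      length(genome_ids),
      replace = TRUE, prob = c(0.6, 0.3, 0.1)
    )
    taxonomy <- tibble(
      genome_id = genome_ids,
      phylum = phyla,
      genus = paste0("g__", phyla, "_", seq_along(genome_ids) %% 3 + 1),
      species = paste0("s__", phyla, "_sp", seq_along(genome_ids))
    )
  }
  list(
    panels = panels,
    proteomes = proteomes,
    metadata = metadata[c(
      "sample_id", "source_kind", "body_site", "oral_subsite", "smoking", "study"
    )],
    taxonomy = taxonomy,
    truth = truth,
    config = config
  )
}

#' Score pipeline output against benchmark truth
#'
#' Precision and recall over planted sequences (`true_homolog` as the
#' positive class; any annotated protein that is not a planted homolog —
#' decoy or background — counts as a false positive), plus per-class
#' resolution: how many members of each decoy class were annotated, and how
#' many were excluded at the stage their truth label predicts. A planted
#' protein absent from the annotation table was stopped by the threshold
#' gates (no qualifying hit).
#'
#' @param truth Truth tibble from [build_benchmark()].
#' @param annotations Annotation tibble or `nde_annotation` object.
#' @return A list: `summary` (one-row tibble with `tp`, `fp`, `fn`,
#'   `precision`, `recall`), `by_class` (per class: `n`, `n_annotated`,
#'   `n_stage_ok`), `details` (truth joined with observed status and stage).
#' @export
score_benchmark <- function(truth, annotations) {
  ann <- annotation_table(annotations)
  truth <- as_tibble(truth)
  need <- c("protein_id", "source_id", "class", "expected_stage")
  missing_cols <- setdiff(need, names(truth))
  if (length(missing_cols) > 0) {
    abort(paste0("truth table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(paste(truth$source_id, truth$protein_id))) {
    abort("duplicate (source_id, protein_id) in truth table")
  }
  if (!"failed_stage" %in% names(ann)) ann$failed_stage <- NA_character_
  obs <- ann |>
    select("protein_id", "source_id", "final_status", "failed_stage")
  details <- truth |>
    left_join(obs, by = c("protein_id", "source_id")) |>
    mutate(
      final_status = dplyr::coalesce(.data$final_status, "excluded"),
      observed_stage = dplyr::case_when(
        .data$final_status == "annotated" ~ "annotated",
        is.na(.data$failed_stage) ~ "thresholds",
        TRUE ~ .data$failed_stage
      ),
      stage_ok = dplyr::case_when(
        .data$expected_stage == "annotated" ~ .data$observed_stage == "annotated",
        .data$expected_stage == "outgroup_filter" ~
          .data$observed_stage %in% c("score_ratio", "tree_filter"),
        TRUE ~ .data$observed_stage == .data$expected_stage
      )
    )
  annotated <- ann |>
    filter(.data$final_status == "annotated") |>
    distinct(.data$protein_id, .data$source_id)
  hom <- filter(details, .data$class == "true_homolog")
  tp <- sum(hom$final_status == "annotated")
  fn <- sum(hom$final_status != "annotated")
  fp <- nrow(annotated) - tp
  summary <- tibble(
    tp = tp, fp = fp, fn = fn,
    precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
    recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  )
  by_class <- details |>
    group_by(.data$class) |>
    summarise(
      n = dplyr::n(),
      n_annotated = sum(.data$final_status == "annotated"),
      n_stage_ok = sum(.data$stage_ok),
      .groups = "drop"
    )
  list(summary = summary, by_class = by_class, details = details)
}
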