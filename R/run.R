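#' Generate a benchmark file set on disk
#'
#' Materialises [build_benchmark()] output in the exact formats the
#' annotation runner consumes: one protein FASTA per source under
#' `proteomes/`, panel FASTAs plus `panel_config.yaml`, `metadata.tsv`,
#' `taxonomy.tsv`, and the ground-truth `truth.tsv`. Deterministic given
#' the configuration seed.
#'
#' @param config A [simulation_config()] object.
#' @param out_dir Output directory (created if needed).
#' @return The benchmark list, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  bench <- build_benchmark(config)
  dir.create(file.path(out_dir, "proteomes"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "panels"), showWarnings = FALSE)
  for (src in unique(bench$proteomes$source_id)) {
    write_fasta(
      filter(bench$proteomes, .data$source_id == src),
      file.path(out_dir, "proteomes", paste0(src, ".faa"))
    )
  }
  type <- unique(bench$panels$nde_type)
  ref_path <- file.path("panels", paste0(type, "_refs.faa"))
  out_path <- file.path("panels", paste0(type, "_outgroups.faa"))
  write_fasta(panel_refs(bench$panels), file.path(out_dir, ref_path))
  cfg <- list(list(references = ref_path))
  names(cfg) <- type
  if (nrow(panel_outs(bench$panels)) > 0) {
    write_fasta(panel_outs(bench$panels), file.path(out_dir, out_path))
    cfg[[type]]$outgroups <- out_path
  }
  yaml::write_yaml(cfg, file.path(out_dir, "panel_config.yaml"))
  readr::write_tsv(bench$metadata, file.path(out_dir, "metadata.tsv"))
  if (!is.null(bench$taxonomy)) {
    readr::write_tsv(bench$taxonomy, file.path(out_dir, "taxonomy.tsv"))
  }
  readr::write_tsv(bench$truth, file.path(out_dir, "truth.tsv"))
  invisible(bench)
}

#' Run the annotation cascade over a directory of proteome FASTAs
#'
#' Loads the panels and metadata, reads every `*.faa`/`*.fasta` file under
#' `proteome_dir` (file stem = source id; source kind looked up in the
#' metadata), runs [annotate_nde()], and writes `annotations.tsv`,
#' `stage_log.tsv`, one Newick tree per family under `trees/`, and a
#' `run_manifest.yaml` echoing the parameters. Outputs are deterministic.
#'
#' @param panel_config Path to the panel YAML (see [load_reference_panel()]).
#' @param proteome_dir Directory of per-source protein FASTA files.
#' @param metadata_path Path to the sample metadata TSV.
#' @param out_dir Output directory.
#' @param scoring,filters Parameter objects.
#' @return The `nde_annotation` object, invisibly.
#' @export
run_annotate <- function(panel_config, proteome_dir, metadata_path, out_dir,
                         scoring = scoring_params(), filters = filter_params()) {
  for (p in c(panel_config, proteome_dir, metadata_path)) {
    if (!file.exists(p)) {
      abort(sprintf("input path does not exist: %s", p))
    }
  }
  panels <- load_reference_panel(panel_config)
  metadata <- read_metadata(metadata_path)
  files <- sort(list.files(proteome_dir, "\\.(faa|fasta|fa)$", full.names = TRUE))
  if (length(files) == 0) {
    abort(sprintf("no FASTA files found under %s", proteome_dir))
  }
  kind_of <- setNames(metadata$source_kind, metadata$sample_id)
  proteomes <- purrr::map(files, function(f) {
    src <- sub("\\.[^.]*$", "", basename(f))
    if (!src %in% names(kind_of)) {
      abort(sprintf("source '%s' missing from metadata", src))
    }
    kind <- kind_of[[src]]
    read_fasta(f, source_id = src, source_kind = kind)
  }) |> bind_rows()
  result <- annotate_nde(proteomes, panels, scoring, filters)

  dir.create(file.path(out_dir, "trees"), recursive = TRUE, showWarnings = FALSE)
  flat <- result$annotations |> select(-"decisions")
  readr::write_tsv(flat, file.path(out_dir, "annotations.tsv"))
  readr::write_tsv(result$stage_log, file.path(out_dir, "stage_log.tsv"))
  for (type in names(result$trees)) {
    ape::write.tree(
      result$trees[[type]],
      file.path(out_dir, "trees", paste0(type, ".nwk"))
    )
  }
  yaml::write_yaml(
    list(
      scoring = result$scoring[c("matrix", "gap_open", "gap_extend", "lambda", "k")],
      filters = unclass(result$filters),
      n_sources = length(files),
      n_annotated = sum(flat$final_status == "annotated")
    ),
    file.path(out_dir, "run_manifest.yaml")
  )
  invisible(result)
}

#' Summarise an annotation run into distribution and prevalence reports
#'
#' Writes `counts_by_source.tsv`, per-rank taxon distributions, all pairwise
#' family taxon overlaps at the genus rank, prevalence tables by body site,
#' oral subsite and (per study) smoking status, and a machine-readable
#' `summary.json` mirroring the report panels.
#'
#' @param annotations_path Path to `annotations.tsv` from [run_annotate()]
#'   (or an annotation tibble / `nde_annotation` object).
#' @param metadata_path Path to the metadata TSV (or a tibble).
#' @param out_dir Output directory.
#' @param taxonomy_path Optional path to the taxonomy TSV (or a tibble).
#' @param prevalence_type Family whose prevalence is reported.
#' @return A list of the computed tables, invisibly.
#' @export
run_summarize <- function(annotations_path, metadata_path, out_dir,
                          taxonomy_path = NULL, prevalence_type = "NicX") {
  ann <- if (is.character(annotations_path)) {
    readr::read_tsv(annotations_path, show_col_types = FALSE)
  } else {
    annotation_table(annotations_path)
  }
  metadata <- if (is.character(metadata_path)) {
    read_metadata(metadata_path)
  } else {
    validate_metadata(metadata_path)
  }
  taxonomy <- NULL
  if (!is.null(taxonomy_path)) {
    taxonomy <- if (is.character(taxonomy_path)) {
      read_taxonomy(taxonomy_path)
    } else {
      validate_taxonomy(taxonomy_path)
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list(counts = count_by_source(ann))
  readr::write_tsv(out$counts, file.path(out_dir, "counts_by_source.tsv"))

  types <- sort(unique(ann$nde_type[ann$final_status == "annotated"]))
  if (!is.null(taxonomy)) {
    ranks <- intersect(TAXONOMY_RANKS, names(taxonomy))
    out$taxon_distribution <- purrr::map(
      setNames(ranks, ranks),
      ~ taxon_distribution(ann, taxonomy, .x)
    )
    for (r in ranks) {
      readr::write_tsv(
        out$taxon_distribution[[r]],
        file.path(out_dir, paste0("taxon_distribution_", r, ".tsv"))
      )
    }
    if (length(types) >= 2 && "genus" %in% ranks) {
      pairs <- utils::combn(types, 2, simplify = FALSE)
      out$taxon_overlap <- purrr::map(
        pairs, ~ taxon_overlap(ann, taxonomy, "genus", .x[1], .x[2])
      ) |> bind_rows()
      readr::write_tsv(out$taxon_overlap, file.path(out_dir, "taxon_overlap_genus.tsv"))
    }
  }

  # subset groupings restrict both the samples and the annotations they carry
  prev_subset <- function(md, group_by) {
    prevalence(
      filter(ann, .data$source_id %in% md$sample_id),
      md, group_by, prevalence_type
    )
  }
  prev_tables <- list(
    body_site = prevalence(ann, metadata, "body_site", prevalence_type),
    oral_subsite = prev_subset(
      filter(metadata, .data$body_site == "oral"), "oral_subsite"
    ),
    smoking = prev_subset(
      filter(metadata, .data$smoking != "unknown"), c("study", "smoking")
    )
  )
  for (nm in names(prev_tables)) {
    readr::write_tsv(
      format_prevalence(prev_tables[[nm]]),
      file.path(out_dir, paste0("prevalence_", nm, ".tsv"))
    )
  }
  out$prevalence <- prev_tables
  jsonlite::write_json(
    purrr::map(
      c(out["counts"], purrr::map(prev_tables, format_prevalence)),
      ~ as.data.frame(.x)
    ),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(out)
}

#' Sum a collection-accounting TSV into totals
#'
#' @param counts_path Path to a counts TSV (columns `study`, `category`,
#'   `count`, optional `body_site`).
#' @param out_path Optional path for the totals TSV.
#' @return The totals tibble from [verify_collection_totals()].
#' @export
run_accounting <- function(counts_path, out_path = NULL) {
  counts <- readr::read_tsv(counts_path, show_col_types = FALSE)
  totals <- verify_collection_totals(counts)
  if (!is.null(out_path)) {
    readr::write_tsv(totals, out_path)
  }
  totals
}
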