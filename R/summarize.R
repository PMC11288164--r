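#' Sequence and positive-source counts per NDE family
#'
#' Counts only `final_status == "annotated"` rows. A source (genome or
#' metagenome) is positive for a family when it contains at least one
#' annotated sequence of that family, so the sequence count is always at
#' least the source count.
#'
#' @param annotations Annotation tibble ([tidy()] of an `nde_annotation`),
#'   or the object itself.
#' @return A tibble: `nde_type`, `source_kind`, `n_sequences`, `n_sources`.
#' @export
count_by_source <- function(annotations) {
  ann <- annotation_table(annotations)
  ann |>
    filter(.data$final_status == "annotated") |>
    group_by(.data$nde_type, .data$source_kind) |>
    summarise(
      n_sequences = dplyr::n(),
      n_sources = dplyr::n_distinct(.data$source_id),
      .groups = "drop"
    )
}

annotation_table <- function(annotations) {
  if (inherits(annotations, "nde_annotation")) {
    return(annotations$annotations)
  }
  as_tibble(annotations)
}

#' Taxonomic composition of NDE-positive genomes
#'
#' For one family and one GTDB rank, the fraction of NDE-positive genomes
#' assigned to each taxon. Genomes without a taxonomy row (or without a
#' label at the rank) are reported as `"Unclassified"`; percentages sum
#' to 100 within the family.
#'
#' @param annotations Annotation tibble or `nde_annotation` object.
#' @param taxonomy Taxonomy tibble (see [read_taxonomy()]).
#' @param rank One of `phylum`, `class`, `order`, `family`, `genus`,
#'   `species`.
#' @param nde_type Family to summarise; default all families present.
#' @return A tibble: `nde_type`, `rank`, `taxon`, `n_genomes`, `percent`.
#' @export
taxon_distribution <- function(annotations, taxonomy, rank,
                               nde_type = NULL) {
  if (!rank %in% TAXONOMY_RANKS) {
    abort(sprintf("unknown rank '%s'", rank))
  }
  taxonomy <- validate_taxonomy(taxonomy)
  pos <- positive_genomes(annotations, nde_type)
  labels <- taxonomy[c("genome_id", intersect(rank, names(taxonomy)))]
  if (!rank %in% names(labels)) labels[[rank]] <- NA_character_
  pos |>
    left_join(labels, by = c(source_id = "genome_id")) |>
    mutate(taxon = dplyr::coalesce(.data[[rank]], "Unclassified")) |>
    group_by(.data$nde_type, .data$taxon) |>
    summarise(n_genomes = dplyr::n(), .groups = "drop_last") |>
    mutate(percent = 100 * .data$n_genomes / sum(.data$n_genomes)) |>
    ungroup() |>
    mutate(rank = rank, .after = "nde_type") |>
    arrange(.data$nde_type, dplyr::desc(.data$percent), .data$taxon)
}

positive_genomes <- function(annotations, nde_type = NULL) {
  ann <- annotation_table(annotations) |>
    filter(.data$final_status == "annotated", .data$source_kind == "genome")
  if (!is.null(nde_type)) {
    ann <- ann[ann$nde_type %in% nde_type, ]
  }
  distinct(ann, .data$nde_type, .data$source_id)
}

#' Taxon overlap between two NDE families
#'
#' Cardinalities of the taxon sets (at one rank) containing at least one
#' positive genome of each family, their intersection and union, plus the
#' union over all families present in the annotations.
#'
#' @inheritParams taxon_distribution
#' @param type_a,type_b The two families to compare.
#' @return A one-row tibble: `rank`, `type_a`, `type_b`, `n_taxa_a`,
#'   `n_taxa_b`, `n_shared`, `n_union`, `n_union_all_types`.
#' @export
taxon_overlap <- function(annotations, taxonomy, rank, type_a, type_b) {
  if (!rank %in% TAXONOMY_RANKS) {
    abort(sprintf("unknown rank '%s'", rank))
  }
  taxonomy <- validate_taxonomy(taxonomy)
  taxa_of <- function(types) {
    pos <- positive_genomes(annotations, types)
    labels <- taxonomy[c("genome_id", intersect(rank, names(taxonomy)))]
    if (!rank %in% names(labels)) labels[[rank]] <- NA_character_
    pos |>
      left_join(labels, by = c(source_id = "genome_id")) |>
      mutate(taxon = dplyr::coalesce(.data[[rank]], "Unclassified")) |>
      pull("taxon") |>
      unique()
  }
  a <- taxa_of(type_a)
  b <- taxa_of(type_b)
  tibble(
    rank = rank, type_a = type_a, type_b = type_b,
    n_taxa_a = length(a), n_taxa_b = length(b),
    n_shared = length(intersect(a, b)),
    n_union = length(union(a, b)),
    n_union_all_types = length(taxa_of(NULL))
  )
}

#' Prevalence of an NDE family across sample groups
#'
#' A sample is positive when it contains at least one annotated homolog of
#' the family; prevalence is the percentage of positive samples per group.
#' Groups with zero samples do not appear. `prevalence_pct` keeps full
#' precision; use [format_prevalence()] for the 1-decimal display
#' convention.
#'
#' @param annotations Annotation tibble or `nde_annotation` object.
#' @param metadata Sample metadata tibble (see [read_metadata()]); every
#'   annotated source must be present.
#' @param group_by Character vector of metadata columns to group on, e.g.
#'   `"body_site"` or `c("study", "smoking")`.
#' @param nde_type Family to assess (default `"NicX"`).
#' @return A tibble of class `nde_prevalence`: grouping columns plus
#'   `n_samples`, `n_positive`, `prevalence_pct`.
#' @export
prevalence <- function(annotations, metadata, group_by = "body_site",
                       nde_type = "NicX") {
  ann <- annotation_table(annotations)
  metadata <- validate_metadata(metadata)
  bad <- setdiff(group_by, names(metadata))
  if (length(bad) > 0) {
    abort(paste0("unknown metadata column(s): ", paste(bad, collapse = ", ")))
  }
  pos_rows <- filter(
    ann, .data$final_status == "annotated", .data$nde_type == !!nde_type
  )
  unknown <- setdiff(pos_rows$source_id, metadata$sample_id)
  if (length(unknown) > 0) {
    abort(sprintf("annotated source '%s' missing from metadata", unknown[1]))
  }
  positive_ids <- unique(pos_rows$source_id)
  out <- metadata |>
    mutate(positive = .data$sample_id %in% positive_ids) |>
    group_by(across(all_of(group_by))) |>
    summarise(
      n_samples = dplyr::n(),
      n_positive = sum(.data$positive),
      .groups = "drop"
    ) |>
    mutate(prevalence_pct = 100 * .data$n_positive / .data$n_samples)
  class(out) <- c("nde_prevalence", class(out))
  attr(out, "nde_type") <- nde_type
  out
}

#' Display-round a prevalence table
#'
#' Prevalence percentages are reported to one decimal, matching the display
#' convention used throughout the package's summaries.
#'
#' @param table An [prevalence()] table.
#' @return The table with `prevalence_pct` rounded to 1 decimal.
#' @export
format_prevalence <- function(table) {
  table$prevalence_pct <- round(table$prevalence_pct, 1)
  table
}

#' Ratio between two groups' prevalences
#'
#' Computed on the displayed (1-decimal) percentages and reported to two
#' decimals, so printed prevalences reproduce printed ratios exactly.
#'
#' @param table A [prevalence()] table with a single grouping column.
#' @param group_a,group_b Group labels (numerator, denominator).
#' @return The ratio, rounded to 2 decimals.
#' @examples
#' tbl <- tibble::tibble(
#'   group = c("tooth", "plaque"), n_samples = c(72, 134),
#'   n_positive = c(55, 50), prevalence_pct = c(76.4, 37.3)
#' )
#' prevalence_ratio(tbl, "tooth", "plaque") # 2.05
#' @export
prevalence_ratio <- function(table, group_a, group_b) {
  table <- as_tibble(table)
  key <- setdiff(names(table), c("n_samples", "n_positive", "prevalence_pct"))
  if (length(key) != 1) {
    abort("prevalence_ratio needs a table with exactly one grouping column")
  }
  pick <- function(g) {
    v <- table$prevalence_pct[table[[key]] == g]
    if (length(v) != 1) {
      abort(sprintf("group '%s' not present exactly once", g))
    }
    round(v, 1)
  }
  a <- pick(group_a)
  b <- pick(group_b)
  if (b == 0) {
    abort(sprintf("prevalence of '%s' is zero; ratio undefined", group_b))
  }
  round(a / b, 2)
}
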