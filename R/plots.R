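#' Plot annotated-sequence and positive-source counts per family
#'
#' Bar chart of [count_by_source()] with one panel for sequence counts and
#' one for positive-source counts, split by genome vs metagenome origin.
#'
#' @param object An `nde_annotation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nde_annotation <- function(object, ...) {
  counts <- count_by_source(object) |>
    tidyr::pivot_longer(
      c("n_sequences", "n_sources"),
      names_to = "measure", values_to = "n"
    ) |>
    mutate(measure = dplyr::recode(.data$measure,
      n_sequences = "sequences", n_sources = "positive sources"
    ))
  ggplot2::ggplot(
    counts,
    ggplot2::aes(x = .data$nde_type, y = .data$n, fill = .data$source_kind)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::scale_fill_manual(
      values = c(genome = "grey20", metagenome = "firebrick")
    ) +
    ggplot2::labs(x = NULL, y = "count", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a prevalence table
#'
#' @param object An [prevalence()] table with one grouping column.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nde_prevalence <- function(object, ...) {
  key <- setdiff(names(object), c("n_samples", "n_positive", "prevalence_pct"))
  df <- as_tibble(object)
  df$group <- interaction(df[key], sep = " / ")
  ggplot2::ggplot(
    df, ggplot2::aes(x = .data$group, y = .data$prevalence_pct)
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.1f%%", .data$prevalence_pct)),
      vjust = -0.4, size = 3
    ) +
    ggplot2::labs(
      x = NULL, y = "prevalence (%)",
      title = paste0(attr(object, "nde_type") %||% "", " prevalence")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a taxon-distribution table
#'
#' Stacked composition bars, one per family, at the summarised rank.
#'
#' @param distribution Output of [taxon_distribution()].
#' @return A ggplot object.
#' @export
plot_taxon_distribution <- function(distribution) {
  ggplot2::ggplot(
    distribution,
    ggplot2::aes(x = .data$nde_type, y = .data$percent, fill = .data$taxon)
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = NULL, y = "% of positive genomes",
      fill = unique(distribution$rank)
    ) +
    ggplot2::theme_minimal()
}
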