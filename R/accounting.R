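#' Sum a collection-accounting table into category and grand totals
#'
#' The input lists, per study (one or more rows each), how many sources it
#' contributed and in which category: `pure_culture_genome` and `mag`
#' (metagenome-assembled genome) roll up into the genome total, while
#' `assembled_metagenome` and `read_metagenome` roll up into the metagenome
#' total. Read-level rows may carry a `body_site`, in which case per-site
#' sample totals are reported as well. All sums are exact integer arithmetic;
#' splitting a study across rows never changes a total.
#'
#' @param counts Tibble with columns `study`, `category`, `count` and
#'   optionally `body_site`.
#' @return A tibble with columns `total` (label) and `value` (integer):
#'   one row per category present, then `genomes_total`, `metagenomes_total`,
#'   `grand_total`, and `samples_<site>` rows for any body sites present.
#' @examples
#' verify_collection_totals(tibble::tibble(
#'   study = c("a", "b", "c"),
#'   category = "pure_culture_genome",
#'   count = c(3324, 97, 216)
#' ))
#' @export
verify_collection_totals <- function(counts) {
  counts <- as_tibble(counts)
  categories <- c(
    "pure_culture_genome", "mag", "assembled_metagenome", "read_metagenome"
  )
  need <- c("study", "category", "count")
  missing <- setdiff(need, names(counts))
  if (length(missing) > 0) {
    abort(paste0("counts table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(counts) == 0) {
    return(tibble(
      total = c("genomes_total", "metagenomes_total", "grand_total"),
      value = 0L
    ))
  }
  if (any(counts$count < 0)) {
    abort("counts must be non-negative")
  }
  if (any(counts$count != round(counts$count))) {
    abort("counts must be integers")
  }
  if (!all(counts$category %in% categories)) {
    abort(paste0(
      "category must be one of: ", paste(categories, collapse = ", ")
    ))
  }
  counts$count <- as.integer(counts$count)
  by_cat <- counts |>
    group_by(.data$category) |>
    summarise(value = sum(.data$count), .groups = "drop") |>
    rename(total = "category")
  cat_sum <- function(cats) {
    sum(by_cat$value[by_cat$total %in% cats])
  }
  rollups <- tibble(
    total = c("genomes_total", "metagenomes_total", "grand_total"),
    value = c(
      cat_sum(c("pure_culture_genome", "mag")),
      cat_sum(c("assembled_metagenome", "read_metagenome")),
      sum(by_cat$value)
    )
  )
  out <- bind_rows(by_cat, rollups)
  if ("body_site" %in% names(counts)) {
    sites <- counts |>
      filter(!is.na(.data$body_site)) |>
      group_by(.data$body_site) |>
      summarise(value = sum(.data$count), .groups = "drop") |>
      mutate(total = paste0("samples_", .data$body_site)) |>
      select("total", "value")
    out <- bind_rows(out, sites)
  }
  out$value <- as.integer(out$value)
  out
}
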