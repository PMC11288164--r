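rec <- function(id, sequence) list(id = id, sequence = sequence)

rec_tbl <- function(...) {
  recs <- list(...)
  tibble::tibble(
    id = vapply(recs, `[[`, "", "id"),
    sequence = vapply(recs, `[[`, "", "sequence")
  )
}

proteome_tbl <- function(..., source_id = "src1", source_kind = "genome") {
  out <- rec_tbl(...)
  out$source_id <- source_id
  out$source_kind <- source_kind
  out
}

# minimal annotation rows for the summarisers
ann_rows <- function(protein_id, source_id, source_kind, nde_type,
                     final_status = "annotated") {
  tibble::tibble(
    protein_id = protein_id, source_id = source_id,
    source_kind = source_kind, nde_type = nde_type,
    final_status = final_status
  )
}

meta_rows <- function(sample_id, body_site = "gut", oral_subsite = "none",
                      smoking = "unknown", source_kind = "metagenome",
                      study = "s1") {
  tibble::tibble(
    sample_id = sample_id, source_kind = source_kind, body_site = body_site,
    oral_subsite = oral_subsite, smoking = smoking, study = study
  )
}

# small, fast benchmark conditions for unit (non-acceptance) tests
small_sim_config <- function(seed = 7) {
  layout <- tibble::tibble(
    body_site = c("gut", "oral", "lung"),
    oral_subsite = c("none", "plaque", "none"),
    smoking = "unknown",
    source_kind = c("genome", "metagenome", "metagenome"),
    study = c("g", "o", "l"),
    n = c(4L, 4L, 2L),
    prevalence = c(0.5, 0.5, 0)
  )
  simulation_config(
    seed = seed, ancestor_length = 250L, n_true_homologs = 5L,
    n_decoys_outgroup_side = 3L, n_decoys_random = 6L, n_decoys_length = 2L,
    n_background = 1L, per_sample_layout = layout
  )
}
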