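test_that("sequence counts and positive-source counts are distinct quantities", {
  ann <- ann_rows(
    protein_id = c("p1", "p2", "p3", "p4", "p5", "p6"),
    source_id = c("g1", "g1", "g1", "g1", "g1", "m1"),
    source_kind = c(rep("genome", 5), "metagenome"),
    nde_type = "NicX"
  )
  counts <- count_by_source(ann)
  expect_equal(counts$n_sequences[counts$source_kind == "genome"], 5)
  expect_equal(counts$n_sources[counts$source_kind == "genome"], 1)
  expect_equal(counts$n_sources[counts$source_kind == "metagenome"], 1)
  expect_true(all(counts$n_sequences >= counts$n_sources))
  # excluded rows never count
  ann2 <- dplyr::mutate(ann, final_status = "excluded")
  expect_equal(nrow(count_by_source(ann2)), 0)
  expect_equal(nrow(count_by_source(ann[0, ])), 0)
})

test_that("taxon distribution recovers planted phylum proportions exactly", {
  ann <- ann_rows(
    protein_id = sprintf("p%02d", 1:10),
    source_id = sprintf("g%02d", 1:10),
    source_kind = "genome", nde_type = "NicX"
  )
  taxonomy <- tibble::tibble(
    genome_id = sprintf("g%02d", 1:10),
    phylum = c(rep("P1", 6), rep("P2", 3), "P3")
  )
  td <- taxon_distribution(ann, taxonomy, "phylum")
  expect_equal(td$percent[td$taxon == "P1"], 60)
  expect_equal(td$percent[td$taxon == "P2"], 30)
  expect_equal(td$percent[td$taxon == "P3"], 10)
  expect_equal(sum(td$percent), 100, tolerance = 0.1)
  # missing taxonomy becomes Unclassified, still summing to 100
  td2 <- taxon_distribution(ann, taxonomy[1:8, ], "phylum")
  expect_equal(td2$percent[td2$taxon == "Unclassified"], 20)
  expect_equal(sum(td2$percent), 100, tolerance = 0.1)
  expect_error(taxon_distribution(ann, taxonomy, "kingdom"), "rank")
})

test_that("taxon overlap reports planted set cardinalities symmetrically", {
  # NdhL in genera t1..t8, NdhB in t6..t11: a=8, b=6, shared=3, union=11
  genera_a <- paste0("t", 1:8)
  genera_b <- paste0("t", 6:11)
  genomes_a <- sprintf("ga%02d", seq_along(genera_a))
  genomes_b <- sprintf("gb%02d", seq_along(genera_b))
  ann <- dplyr::bind_rows(
    ann_rows(paste0("pa", 1:8), genomes_a, "genome", "NdhL"),
    ann_rows(paste0("pb", 1:6), genomes_b, "genome", "NdhB")
  )
  taxonomy <- tibble::tibble(
    genome_id = c(genomes_a, genomes_b), genus = c(genera_a, genera_b)
  )
  ov <- taxon_overlap(ann, taxonomy, "genus", "NdhL", "NdhB")
  expect_equal(ov$n_taxa_a, 8)
  expect_equal(ov$n_taxa_b, 6)
  expect_equal(ov$n_shared, 3)
  expect_equal(ov$n_union, 11)
  expect_equal(ov$n_union_all_types, 11)
  swapped <- taxon_overlap(ann, taxonomy, "genus", "NdhB", "NdhL")
  expect_equal(swapped$n_shared, ov$n_shared)
  expect_equal(swapped$n_union, ov$n_union)
})

test_that("prevalence counts positive samples, not sequences", {
  md <- meta_rows(sprintf("s%02d", 1:10), body_site = "gut")
  ann <- ann_rows(
    protein_id = c("p1", "p2", "p3"),
    source_id = c("s01", "s01", "s02"), # duplicate homologs in s01
    source_kind = "metagenome", nde_type = "NicX"
  )
  tbl <- prevalence(ann, md, "body_site", "NicX")
  expect_equal(tbl$n_samples, 10)
  expect_equal(tbl$n_positive, 2)
  expect_equal(tbl$prevalence_pct, 20)
  # duplicating annotated rows changes nothing
  expect_equal(prevalence(dplyr::bind_rows(ann, ann), md, "body_site", "NicX"), tbl)
  # zero positives and all positives
  none <- prevalence(ann[0, ], md, "body_site", "NicX")
  expect_equal(none$prevalence_pct, 0)
  md7 <- meta_rows(sprintf("s%02d", 1:7))
  all_pos <- prevalence(
    ann_rows(sprintf("p%d", 1:7), sprintf("s%02d", 1:7), "metagenome", "NicX"),
    md7, "body_site", "NicX"
  )
  expect_equal(all_pos$prevalence_pct, 100)
  # unknown sample id is an error that names the culprit
  bad <- ann_rows("px", "missing_sample", "metagenome", "NicX")
  expect_error(prevalence(bad, md, "body_site", "NicX"), "missing_sample")
})

test_that("prevalence ratios reproduce printed two-decimal arithmetic", {
  tbl <- tibble::tibble(
    oral_subsite = c("tooth", "plaque", "saliva"),
    n_samples = c(72, 134, 89),
    n_positive = c(55, 50, 3),
    prevalence_pct = 100 * c(55 / 72, 50 / 134, 3 / 89)
  )
  disp <- format_prevalence(tbl)
  expect_equal(disp$prevalence_pct, c(76.4, 37.3, 3.4))
  expect_equal(prevalence_ratio(tbl, "tooth", "plaque"), 2.05)
  expect_equal(prevalence_ratio(tbl, "plaque", "plaque"), 1.00)
  even <- tibble::tibble(
    g = c("a", "b"), n_samples = c(10, 10), n_positive = c(5, 5),
    prevalence_pct = c(50, 25)
  )
  expect_equal(prevalence_ratio(even, "a", "b"), 2.00)
  zero <- tibble::tibble(
    g = c("a", "b"), n_samples = c(4, 4), n_positive = c(2, 0),
    prevalence_pct = c(50, 0)
  )
  expect_error(prevalence_ratio(zero, "a", "b"), "undefined")
})
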