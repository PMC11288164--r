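test_that("FASTA entries parse with first-token ids, uppercasing and order kept", {
  f <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">g1 some description", "mkv", ">g2", "MKVL", "ITG"), f)
  recs <- read_fasta(f, source_id = "s1", source_kind = "metagenome")
  expect_equal(recs$id, c("g1", "g2"))
  expect_equal(recs$sequence, c("MKV", "MKVLITG"))
  expect_equal(unique(recs$source_kind), "metagenome")
})

test_that("empty FASTA gives an empty record table", {
  f <- withr::local_tempfile(fileext = ".faa")
  writeLines(character(0), f)
  expect_equal(nrow(read_fasta(f)), 0)
})

test_that("malformed FASTA input fails with the offending line number", {
  f <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">g1", "MKB"), f) # B is not in the alphabet
  expect_error(read_fasta(f), "line 2")
  writeLines(c("MKV"), f)
  expect_error(read_fasta(f), "line 1")
  writeLines(c(">g1", "MKV", ">g1", "MKL"), f)
  expect_error(read_fasta(f), "duplicate")
})

test_that("FASTA write/read round-trips arbitrary legal records", {
  withr::local_seed(101)
  recs <- tibble::tibble(
    id = sprintf("p%02d", 1:50),
    sequence = vapply(
      sample(1:180, 50, replace = TRUE),
      function(n) rand_seq(n, with_x = TRUE), ""
    )
  )
  f <- withr::local_tempfile(fileext = ".faa")
  write_fasta(recs, f, width = 37)
  back <- read_fasta(f, source_id = "x")
  expect_equal(back[c("id", "sequence")], recs)
})

test_that("panel construction enforces non-empty references and disjoint ids", {
  refs <- rec_tbl(rec("r1", "MKVLITG"))
  outs <- rec_tbl(rec("o1", "MWWAAKL"))
  p <- reference_panel(refs, "NicX", outs)
  expect_s3_class(p, "nde_panels")
  expect_equal(sum(p$role == "reference"), 1)
  # NicA2 may legitimately have no outgroups
  p2 <- reference_panel(refs, "NicA2")
  expect_equal(sum(p2$role == "outgroup"), 0)
  expect_error(reference_panel(rec_tbl(), "NicX"), "no reference")
  expect_error(
    reference_panel(refs, "NicX", rec_tbl(rec("r1", "MAAAA"))),
    "overlap"
  )
  expect_error(reference_panel(refs, "NdhQ"), "nde_type")
})

test_that("a five-family panel configuration loads, outgroup-less family included", {
  dir <- withr::local_tempdir()
  withr::local_seed(11)
  cfg <- list()
  for (type in c("NdhB", "NdhL", "NicX", "NicA1", "NicA2")) {
    rf <- file.path(dir, paste0(type, "_refs.faa"))
    write_fasta(rec_tbl(rec(paste0(type, "_ref"), rand_seq(80))), rf)
    cfg[[type]] <- list(references = basename(rf))
    if (type != "NicA2") {
      of <- file.path(dir, paste0(type, "_out.faa"))
      write_fasta(rec_tbl(rec(paste0(type, "_out"), rand_seq(80))), of)
      cfg[[type]]$outgroups <- basename(of)
    }
  }
  cfg_path <- file.path(dir, "panels.yaml")
  yaml::write_yaml(cfg, cfg_path)
  panels <- load_reference_panel(cfg_path)
  expect_setequal(unique(panels$nde_type), c("NdhB", "NdhL", "NicX", "NicA1", "NicA2"))
  expect_equal(sum(panels$nde_type == "NicA2" & panels$role == "outgroup"), 0)
  expect_equal(sum(panels$role == "reference"), 5)
})

test_that("metadata validation maps stray levels to unknown and checks subsites", {
  md <- meta_rows(c("a", "b"), body_site = c("gut", "weird"))
  out <- ndescreen:::validate_metadata(md)
  expect_equal(out$body_site, c("gut", "unknown"))
  bad <- meta_rows("a", body_site = "gut", oral_subsite = "tooth")
  expect_error(ndescreen:::validate_metadata(bad), "oral")
})

test_that("collection totals are exact, additive and order-invariant", {
  counts <- tibble::tibble(
    study = c("l1", "l2", "l3", "p1", "p2", "p3"),
    category = c(rep("read_metagenome", 3), rep("pure_culture_genome", 3)),
    count = c(38, 47, 18, 3324, 97, 216),
    body_site = c("lung", "lung", "lung", NA, NA, NA)
  )
  tot <- verify_collection_totals(counts)
  val <- function(t, k) t$value[t$total == k]
  expect_identical(val(tot, "samples_lung"), 103L)
  expect_identical(val(tot, "pure_culture_genome"), 3637L)
  # order invariance and additivity under row splitting
  shuffled <- counts[sample(nrow(counts)), ]
  expect_equal(
    dplyr::arrange(verify_collection_totals(shuffled), total),
    dplyr::arrange(tot, total)
  )
  split <- dplyr::bind_rows(
    dplyr::mutate(counts[1, ], count = 20),
    dplyr::mutate(counts[1, ], count = 18, study = "l1b"),
    counts[-1, ]
  )
  expect_equal(
    dplyr::arrange(verify_collection_totals(split), total),
    dplyr::arrange(tot, total)
  )
  # empty and invalid input
  expect_true(all(verify_collection_totals(counts[0, ])$value == 0))
  expect_error(
    verify_collection_totals(dplyr::mutate(counts, count = -count)),
    "non-negative"
  )
})
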