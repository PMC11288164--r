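sc <- scoring_params()

test_that("self-alignment yields full identity, coverage and the self-score", {
  h <- align_local(rec("r", "MKVLITG"), rec("c", "MKVLITG"), sc)
  expect_equal(h$identity_pct, 100)
  expect_equal(h$ref_coverage_pct, 100)
  self <- sum(diag(sc$sub_matrix[
    strsplit("MKVLITG", "")[[1]], strsplit("MKVLITG", "")[[1]]
  ]))
  expect_equal(h$raw_score, self)
})

test_that("local score matches the independent DP oracle, frozen case included", {
  expect_equal(oracle_sw("HEAGAWGHEE", "PAWHEAE"), 17)
  h <- align_local(rec("a", "HEAGAWGHEE"), rec("b", "PAWHEAE"), sc)
  expect_equal(h$raw_score, 17)
  withr::local_seed(42)
  for (i in 1:40) {
    a <- rand_seq(sample(5:60, 1), with_x = i %% 5 == 0)
    b <- rand_seq(sample(5:60, 1), with_x = i %% 7 == 0)
    o <- oracle_sw(a, b)
    got <- align_local(rec("a", a), rec("b", b), sc)
    if (o <= 0) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$raw_score, o)
    }
  }
})

test_that("all-mismatch pairs yield no hit and raw score is symmetric", {
  expect_equal(nrow(align_local(rec("a", "AAAA"), rec("b", "WWWW"), sc)), 0)
  withr::local_seed(9)
  for (i in 1:20) {
    a <- rand_seq(sample(10:50, 1))
    b <- rand_seq(sample(10:50, 1))
    ab <- align_local(rec("a", a), rec("b", b), sc)
    ba <- align_local(rec("b", b), rec("a", a), sc)
    sab <- if (nrow(ab) == 0) 0 else ab$raw_score
    sba <- if (nrow(ba) == 0) 0 else ba$raw_score
    expect_equal(sab, sba)
  }
})

test_that("bit scores follow the Karlin-Altschul form and are monotone", {
  expect_equal(bit_score(0, sc), -log(0.041) / log(2), tolerance = 1e-12)
  expect_equal(bit_score(0, sc), 4.608, tolerance = 1e-3)
  expect_true(bit_score(10, sc) < bit_score(11, sc))
  unit <- scoring_params(lambda = log(2), k = 1)
  expect_equal(bit_score(c(0, 7, 123), unit), c(0, 7, 123))
  expect_error(bit_score(-1, sc), ">= 0")
})

test_that("gates keep boundary values and exclude strictly beyond them", {
  hit <- function(identity, coverage, qlen, slen) {
    tibble::tibble(
      query_id = "r", subject_id = "c", raw_score = 100, bit_score = 40,
      identity_pct = identity, ref_coverage_pct = coverage,
      qlen = qlen, slen = slen, aln_len = 10L, mismatch = 0L, gapopen = 0L,
      qstart = 1L, qend = 10L, sstart = 1L, send = 10L
    )
  }
  fl <- filter_params()
  # all three boundaries simultaneously: kept
  expect_true(hit_passes_thresholds(hit(30, 40, 400, 200), fl)$passed)
  expect_true(hit_passes_thresholds(hit(30, 40, 400, 600), fl)$passed)
  just_id <- hit_passes_thresholds(hit(29.9, 80, 400, 400), fl)
  expect_false(just_id$passed)
  expect_equal(just_id$failed_rules[[1]], "identity")
  just_cov <- hit_passes_thresholds(hit(50, 39.9, 400, 400), fl)
  expect_equal(just_cov$failed_rules[[1]], "coverage")
  just_len <- hit_passes_thresholds(hit(50, 80, 400, 601), fl)
  expect_equal(just_len$failed_rules[[1]], "length")
  expect_false(hit_passes_thresholds(hit(50, 80, 400, 199), fl)$passed)
})

test_that("raising the identity gate never adds candidates", {
  withr::local_seed(5)
  anc <- rand_seq(200)
  prot <- proteome_tbl(
    rec("p1", evolve_protein(anc, 0.8, id = "p1")$sequence),
    rec("p2", evolve_protein(anc, 0.45, id = "p2")$sequence),
    rec("p3", rand_seq(200))
  )
  panel <- reference_panel(rec_tbl(rec("ref1", anc)), "NicX")
  loose <- find_candidates(prot, panel, sc, filter_params(min_identity_pct = 30))
  tight <- find_candidates(prot, panel, sc, filter_params(min_identity_pct = 60))
  expect_true(all(tight$protein_id %in% loose$protein_id))
  expect_true(nrow(tight) <= nrow(loose))
})

test_that("candidate search deduplicates per protein and ignores input order", {
  withr::local_seed(6)
  anc <- rand_seq(150)
  r1 <- evolve_protein(anc, 0.95, id = "refA")
  r2 <- evolve_protein(anc, 0.9, id = "refB")
  panel <- reference_panel(
    rec_tbl(rec("refA", r1$sequence), rec("refB", r2$sequence)), "NicX"
  )
  prot <- proteome_tbl(
    rec("exact", r1$sequence),       # exact copy of a reference
    rec("homol", evolve_protein(anc, 0.7, id = "h")$sequence),
    rec("noise", rand_seq(150))
  )
  cands <- find_candidates(prot, panel, sc)
  expect_equal(sum(cands$protein_id == "exact"), 1) # hit by both refs, one row
  exact <- cands[cands$protein_id == "exact", ]
  expect_equal(exact$identity_pct, 100)
  expect_equal(exact$query_id, "refA") # best hit recorded
  expect_false("noise" %in% cands$protein_id)
  shuffled <- find_candidates(prot[c(3, 1, 2), ], panel, sc)
  expect_identical(cands, shuffled)
  expect_equal(nrow(find_candidates(prot[0, ], panel, sc)), 0)
})
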