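sc <- scoring_params()

test_that("Kimura correction matches the closed form and saturates", {
  same <- kimura_distance(rec("a", "MKVLITGAA"), rec("b", "MKVLITGAA"), sc)
  expect_equal(same, 0)
  # closed form at p = 0.5 and the saturation rule
  expect_equal(
    ndescreen:::kimura_from_counts(5, 5), -log(0.45),
    tolerance = 1e-12
  )
  expect_equal(-log(1 - 0.5 - 0.2 * 0.25), 0.7985, tolerance = 1e-4)
  expect_equal(ndescreen:::kimura_from_counts(1, 9), 5.0)
  expect_equal(ndescreen:::kimura_from_counts(0, 0), 5.0)
})

test_that("NJ recovers the 4-leaf additive tree with its branch lengths", {
  labs <- c("A", "B", "C", "D")
  dm <- matrix(c(
    0, 5, 7, 8,
    5, 0, 8, 9,
    7, 8, 0, 9,
    8, 9, 9, 0
  ), 4, 4, dimnames = list(labs, labs))
  # four-point condition: the two larger sums are equal
  sums <- sort(c(
    dm["A", "B"] + dm["C", "D"],
    dm["A", "C"] + dm["B", "D"],
    dm["A", "D"] + dm["B", "C"]
  ))
  expect_equal(sums[2], sums[3])
  tree <- nj_tree(dm)
  # additive input: patristic distances reproduce the matrix exactly
  pm <- ape::cophenetic.phylo(tree)[labs, labs]
  expect_equal(pm, dm, tolerance = 1e-12)
  # (A,B) vs (C,D) split with terminal branches 2,3,4,5 and internal 1
  expect_setequal(round(tree$edge.length, 9), c(2, 3, 1, 4, 5))
  expect_equal(patristic_distance(tree, "A", "C"), 7)
  expect_equal(patristic_distance(tree, "A", "A"), 0)
  expect_equal(
    patristic_distance(tree, "B", "D"), patristic_distance(tree, "D", "B")
  )
  expect_error(patristic_distance(tree, "A", "Z"), "tips")
})

test_that("3-leaf NJ matches the closed three-point formulas", {
  labs <- c("x", "y", "z")
  dm <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3, dimnames = list(labs, labs))
  tree <- nj_tree(dm)
  edge_of <- function(tip) tree$edge.length[tree$edge[, 2] == match(tip, tree$tip.label)]
  expect_equal(edge_of("x"), (3 + 4 - 5) / 2)
  expect_equal(edge_of("y"), (3 + 5 - 4) / 2)
  expect_equal(edge_of("z"), (4 + 5 - 3) / 2)
})

test_that("NJ round-trips random 5-leaf trees through their patristic matrices", {
  withr::local_seed(77)
  for (i in 1:20) {
    t0 <- ape::unroot(ape::rtree(5, br = function(n) runif(n, 0.1, 2)))
    dm <- ape::cophenetic.phylo(t0)
    t1 <- nj_tree(dm)
    pm <- ape::cophenetic.phylo(t1)[rownames(dm), colnames(dm)]
    expect_lt(max(abs(pm - dm)), 1e-9)
    expect_equal(as.numeric(ape::dist.topo(t0, t1)), 0)
  }
})

test_that("distance-matrix validation rejects malformed input", {
  m <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_tree(m), "at least 3")
  labs <- c("a", "b", "c")
  asym <- matrix(c(0, 1, 2, 3, 0, 1, 2, 1, 0), 3, 3, dimnames = list(labs, labs))
  expect_error(nj_tree(asym), "symmetric")
})

test_that("tree filter keeps reference-like and drops outgroup-like candidates", {
  withr::local_seed(55)
  anc <- rand_seq(300)
  outf <- evolve_protein(anc, 0.5, id = "outf")
  refs <- rec_tbl(
    rec("r1", evolve_protein(anc, 0.9, id = "r1")$sequence),
    rec("r2", evolve_protein(anc, 0.85, id = "r2")$sequence)
  )
  outs <- rec_tbl(
    rec("o1", evolve_protein(outf, 0.9, id = "o1")$sequence),
    rec("o2", evolve_protein(outf, 0.85, id = "o2")$sequence)
  )
  panel <- reference_panel(refs, "NicX", outs)
  cands <- tibble::tibble(
    protein_id = c("ref_like", "out_like"),
    source_id = "s1",
    sequence = c(
      refs$sequence[1], # identical to a reference: d_ref = 0
      evolve_protein(outf, 0.95, id = "d")$sequence # inside outgroup clade
    )
  )
  res <- tree_filter(cands, panel, filter_params(), sc)
  expect_true(res$tree_passed[res$protein_id == "ref_like"])
  expect_equal(res$d_ref[res$protein_id == "ref_like"], 0)
  expect_false(res$tree_passed[res$protein_id == "out_like"])
  expect_true(res$d_out[res$protein_id == "out_like"] <
    res$d_ref[res$protein_id == "out_like"])
  expect_s3_class(attr(res, "tree"), "phylo")
})

test_that("equal reference and outgroup distance is excluded under any margin", {
  # candidate, one reference and one outgroup all identical sequences:
  # d_ref = d_out = 0, and 'close to or bigger than' means exclusion
  s <- rand_seq(60)
  panel <- reference_panel(
    rec_tbl(rec("r1", s)), "NicX", rec_tbl(rec("o1", s))
  )
  cands <- tibble::tibble(protein_id = "c1", source_id = "s1", sequence = s)
  res <- tree_filter(cands, panel, filter_params(tree_margin = 1), sc)
  expect_false(res$tree_passed)
})

test_that("families without outgroups bypass the tree filter", {
  withr::local_seed(56)
  panel <- reference_panel(rec_tbl(rec("r1", rand_seq(100))), "NicA2")
  cands <- tibble::tibble(
    protein_id = "c1", source_id = "s1",
    sequence = panel$sequence[1]
  )
  res <- tree_filter(cands, panel, filter_params(), sc)
  expect_true(res$tree_passed)
  expect_true(is.na(res$d_out))
})

test_that("shrinking the tree margin never enlarges the keep set", {
  withr::local_seed(57)
  anc <- rand_seq(250)
  outf <- evolve_protein(anc, 0.5, id = "outf")
  panel <- reference_panel(
    rec_tbl(rec("r1", evolve_protein(anc, 0.9, id = "r1")$sequence)),
    "NicX",
    rec_tbl(rec("o1", evolve_protein(outf, 0.9, id = "o1")$sequence))
  )
  cands <- tibble::tibble(
    protein_id = sprintf("c%d", 1:6),
    source_id = "s1",
    sequence = vapply(
      seq(0.45, 0.95, length.out = 6),
      function(t) evolve_protein(anc, t, id = "c")$sequence, ""
    )
  )
  kept <- lapply(c(1, 0.9, 0.6, 0.3), function(m) {
    res <- tree_filter(cands, panel, filter_params(tree_margin = m), sc)
    res$protein_id[res$tree_passed]
  })
  for (i in 2:length(kept)) {
    expect_true(all(kept[[i]] %in% kept[[i - 1]]))
  }
})
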