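#' Kimura-corrected protein distance between two sequences
#'
#' An end-gap-free global alignment is computed; over its gap-free columns
#' the uncorrected distance is `p = 1 - identical / aligned pairs`, and the
#' Kimura correction `d = -ln(1 - p - 0.2 p^2)` is applied. Distances
#' saturate: `p >= 0.85` (where the correction diverges) maps to a fixed
#' ceiling of 5.0, as does a pair with no aligned residue pairs at all.
#'
#' @param a,b One-row record tibbles or lists with `id` and `sequence`.
#' @param scoring A [scoring_params()] object.
#' @return A single non-negative distance.
#' @examples
#' kimura_distance(list(id = "x", sequence = "MKVLITG"),
#'                 list(id = "y", sequence = "MKVLITG"))
#' @export
kimura_distance <- function(a, b, scoring = scoring_params()) {
  a <- as_record(a)
  b <- as_record(b)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(a$sequence),
    subject = Biostrings::AAString(b$sequence),
    substitutionMatrix = scoring$sub_matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
    type = "overlap"
  )
  kimura_from_counts(Biostrings::nmatch(aln), Biostrings::nmismatch(aln))
}

KIMURA_CEILING <- 5.0

kimura_from_counts <- function(nmatch, nmismatch) {
  pairs <- nmatch + nmismatch
  p <- ifelse(pairs == 0, 1, 1 - nmatch / pairs)
  ifelse(p >= 0.85, KIMURA_CEILING, -log(1 - p - 0.2 * p^2))
}

#' Pairwise Kimura distance matrix for a set of proteins
#'
#' @param records Record tibble with unique `id`s.
#' @param scoring A [scoring_params()] object.
#' @return A square symmetric numeric matrix with zero diagonal, labelled by
#'   record id.
#' @export
protein_distance_matrix <- function(records, scoring = scoring_params()) {
  records <- as_tibble(records)
  n <- nrow(records)
  if (anyDuplicated(records$id)) {
    abort("distance matrix requires unique record ids")
  }
  m <- matrix(0, n, n, dimnames = list(records$id, records$id))
  if (n < 2) {
    return(m)
  }
  seqs <- Biostrings::AAStringSet(records$sequence)
  for (i in seq_len(n - 1)) {
    rest <- (i + 1):n
    aln <- Biostrings::pairwiseAlignment(
      pattern = seqs[rest], subject = seqs[[i]],
      substitutionMatrix = scoring$sub_matrix,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
      type = "overlap"
    )
    d <- kimura_from_counts(Biostrings::nmatch(aln), Biostrings::nmismatch(aln))
    m[i, rest] <- d
    m[rest, i] <- d
  }
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou--Nei neighbor joining; negative estimated branch lengths
#' are clamped to zero so patristic distances stay non-negative. On an
#' additive matrix the generating topology and branch lengths are recovered.
#'
#' @param dm Square symmetric numeric matrix with zero diagonal and at least
#'   three labelled tips.
#' @return An unrooted `phylo` tree (ape).
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) != ncol(dm) || is.null(rownames(dm))) {
    abort("dm must be a square labelled matrix")
  }
  if (nrow(dm) < 3) {
    abort("neighbor joining needs at least 3 tips")
  }
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8))) {
    abort("dm must be symmetric")
  }
  if (any(!is.finite(dm)) || any(diag(dm) != 0) || any(dm < 0)) {
    abort("dm must be finite and non-negative with a zero diagonal")
  }
  tree <- ape::nj(stats::as.dist(dm))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Patristic distance between two tips
#'
#' Sum of branch lengths along the unique path between two leaves.
#'
#' @param tree A `phylo` tree.
#' @param leaf_a,leaf_b Tip labels.
#' @return A single non-negative distance.
#' @export
patristic_distance <- function(tree, leaf_a, leaf_b) {
  if (!all(c(leaf_a, leaf_b) %in% tree$tip.label)) {
    abort("both leaves must be tips of the tree")
  }
  if (leaf_a == leaf_b) {
    return(0)
  }
  pm <- ape::cophenetic.phylo(tree)
  pm[leaf_a, leaf_b]
}
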