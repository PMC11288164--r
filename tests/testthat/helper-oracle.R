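# Independent brute-force oracles, written before and apart from the package
# implementation. oracle_sw() is a plain three-state Gotoh dynamic program in
# R: a gap of length L costs open + L * ext, local alignments may start and
# end anywhere, and the empty alignment scores 0.

oracle_blosum62_x0 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  letters <- c(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], "X")
  m <- e$BLOSUM62[letters, letters]
  m["X", ] <- 0
  m[, "X"] <- 0
  m
}

oracle_sw <- function(a, b, mat = oracle_blosum62_x0(), open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  neg <- -1e9
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(neg, n + 1, m + 1) # gap in b (vertical)
  Iy <- matrix(neg, n + 1, m + 1) # gap in a (horizontal)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- mat[av[i - 1], bv[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1] + s, Ix[i - 1, j - 1] + s, Iy[i - 1, j - 1] + s)
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

rand_seq <- function(len, with_x = FALSE) {
  pool <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  if (with_x) pool <- c(pool, "X")
  paste(sample(pool, len, replace = TRUE), collapse = "")
}
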