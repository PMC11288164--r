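#' Alignment scoring parameters
#'
#' Bundles the substitution matrix, affine gap penalties and the
#' Karlin--Altschul constants used to express raw alignment scores in bits.
#' Defaults mirror the ungapped BLOSUM62 search convention (gap open 11,
#' gap extend 1, lambda 0.267, K 0.041): a gap of length L costs
#' `gap_open + L * gap_extend`.
#'
#' @param matrix Substitution matrix name; only `"BLOSUM62"` ships with the
#'   package. `X` is treated as fully ambiguous and scores 0 against every
#'   residue, including itself.
#' @param gap_open Positive integer gap-opening penalty.
#' @param gap_extend Positive integer gap-extension penalty (per residue).
#' @param lambda,k Karlin--Altschul parameters; `bits = (lambda * raw - ln k) / ln 2`.
#' @return An object of class `nde_scoring`: a list with the parameters plus
#'   the resolved numeric substitution matrix (`$sub_matrix`).
#' @examples
#' sc <- scoring_params()
#' sc$sub_matrix["A", "A"]
#' @export
scoring_params <- function(matrix = "BLOSUM62", gap_open = 11L, gap_extend = 1L,
                           lambda = 0.267, k = 0.041) {
  if (!identical(matrix, "BLOSUM62")) {
    abort(sprintf("unknown substitution matrix '%s'", matrix))
  }
  gap_open <- as.integer(gap_open)
  gap_extend <- as.integer(gap_extend)
  if (gap_extend < 1L || gap_open < gap_extend) {
    abort("gap penalties must satisfy gap_open >= gap_extend >= 1")
  }
  if (!is.numeric(lambda) || lambda <= 0 || !is.numeric(k) || k <= 0) {
    abort("lambda and k must be positive reals")
  }
  structure(
    list(
      matrix = matrix, gap_open = gap_open, gap_extend = gap_extend,
      lambda = lambda, k = k, sub_matrix = blosum62_x0()
    ),
    class = "nde_scoring"
  )
}

# BLOSUM62 restricted to the 20 standard residues plus X, with the X row and
# column zeroed (X is uninformative rather than mildly penalised).
blosum62_x0 <- function() {
  cached <- get0(".blosum62_x0", envir = .ndescreen_cache)
  if (!is.null(cached)) {
    return(cached)
  }
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
  m["X", ] <- 0
  m[, "X"] <- 0
  storage.mode(m) <- "double"
  assign(".blosum62_x0", m, envir = .ndescreen_cache)
  m
}

.ndescreen_cache <- new.env(parent = emptyenv())

#' Convert a raw alignment score to bits
#'
#' Karlin--Altschul normalization, `(lambda * raw - ln k) / ln 2`, strictly
#' increasing in the raw score. This is the scale on which the outgroup
#' score-ratio rule operates.
#'
#' @param raw_score Non-negative raw score(s).
#' @param scoring A [scoring_params()] object.
#' @return Numeric vector of bit scores.
#' @examples
#' bit_score(0, scoring_params()) # (-ln 0.041)/ln 2, about 4.61 bits
#' @export
bit_score <- function(raw_score, scoring = scoring_params()) {
  stopifnot(inherits(scoring, "nde_scoring"))
  if (any(raw_score < 0)) {
    abort("raw_score must be >= 0")
  }
  (scoring$lambda * raw_score - log(scoring$k)) / log(2)
}
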