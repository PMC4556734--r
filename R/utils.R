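#' Round half away from zero
#'
#' Deterministic rounding used wherever a fractional count (edges to retain,
#' hubs to select) must become an integer: 51.5 -> 52, -2.5 -> -3.  R's
#' `round()` rounds half to even and is not used for these counts.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Deterministic per-stage seed derived from a master seed
#'
#' Mixes a master integer seed with a stage name so that independent pipeline
#' stages consume independent, reproducible random streams, and changing one
#' stage's settings (e.g. the permutation count) does not perturb another
#' stage's draws.  The result is always in `[1, 2^31 - 2]`.
#'
#' @param master integer master seed.
#' @param stage character scalar naming the stage.
#' @return integer seed.
#' @export
stage_seed <- function(master, stage) {
  stopifnot(length(master) == 1, is.finite(master), is.character(stage),
            length(stage) == 1)
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000003
  as.integer(1 + (abs(master) %% 1048573) * 1009 + h) %% (2^31 - 2) + 1L
}

# Internal: consistent ordering of the M = N(N-1)/2 node pairs.  All edge
# vectors in the package (FC stacks, distances, per-edge correlations) use
# R's column-major upper.tri order; `edge_index` materialises the (i, j)
# pairs in that same order.
edge_index <- function(n) {
  ut <- upper.tri(matrix(0, n, n))
  idx <- which(ut, arr.ind = TRUE)
  # which(arr.ind) already returns column-major order
  data.frame(i = idx[, 1], j = idx[, 2])
}

upper_tri_values <- function(m) m[upper.tri(m)]

`%||%` <- function(a, b) if (is.null(a)) b else a
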