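#' Pearson correlation matrix over nodes
#'
#' Functional connectivity as the pairwise Pearson correlation of node time
#' series.  Constant columns make the correlation undefined and are
#' reported as an error naming the offending nodes.
#'
#' @param ts `T x N` time-series matrix, `T >= 3`.
#' @return symmetric `N x N` matrix with unit diagonal.
#' @export
correlation_matrix <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3) stop("need at least 3 timepoints for a correlation")
  sds <- apply(ts, 2, sd)
  if (any(sds == 0))
    stop("constant time series for node(s): ",
         paste(which(sds == 0), collapse = ", "),
         " (correlation undefined)")
  r <- cor(ts)
  r <- (r + t(r)) / 2
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  r
}

#' Proportional threshold of a connectivity matrix
#'
#' Retains the strongest fraction `density` of the `M = N(N-1)/2` unique
#' connection weights and zeroes the rest, yielding a weighted network of
#' fixed edge density for every subject.  "Strongest" means the largest
#' signed correlation by default; `mode = "absolute"` ranks by magnitude
#' instead.  The retained count is `round(density * M)` with half rounded
#' away from zero, and ties at the cut are broken by (row, column)
#' lexicographic order so the result is deterministic.
#'
#' @param fc symmetric `N x N` connectivity matrix.
#' @param density fraction of pairs to retain, in (0, 1].
#' @param mode ranking rule, `"signed"` (default) or `"absolute"`.
#' @return a `weighted_network`: list with `weights` (`N x N`, symmetric,
#'   zero diagonal), `density`, `retained_count`.
#' @examples
#' fc <- correlation_matrix(matrix(rnorm(400), 20, 20))
#' net <- proportional_threshold(fc, density = 0.2)
#' net$retained_count
#' @export
proportional_threshold <- function(fc, density = 0.2,
                                   mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  fc <- as.matrix(fc)
  n <- nrow(fc)
  if (n != ncol(fc)) stop("connectivity matrix must be square")
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  m <- n * (n - 1) / 2
  k <- max(1L, as.integer(round_half_away(density * m)))

  ei <- edge_index(n)
  vals <- upper_tri_values(fc)
  key <- if (mode == "absolute") -abs(vals) else -vals
  ord <- order(key, ei$i, ei$j)
  keep <- ord[seq_len(k)]
  if (mode == "signed" && any(vals[keep] < 0))
    warning("requested density exceeds the positive-weight fraction; ",
            "negative weights retained")

  w <- matrix(0, n, n)
  w[cbind(ei$i[keep], ei$j[keep])] <- vals[keep]
  w <- w + t(w)
  structure(list(weights = w, density = density, retained_count = k),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("weighted network: %d nodes, %d edges retained (density %.3g)\n",
              nrow(x$weights), x$retained_count, x$density))
  invisible(x)
}

#' Whole-brain mean connectivity
#'
#' Mean of the retained connection weights of a thresholded network
#' (default), or the mean over all `N(N-1)/2` node pairs with discarded
#' pairs counted as zero (`mode = "all_pairs"`).
#'
#' @param net a `weighted_network`.
#' @param mode `"retained"` (default) or `"all_pairs"`.
#' @return scalar mean weight.
#' @export
mean_connectivity <- function(net, mode = c("retained", "all_pairs")) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "weighted_network"))
  if (net$retained_count < 1) stop("network has no retained edges")
  total <- sum(upper_tri_values(net$weights))
  n <- nrow(net$weights)
  denom <- if (mode == "retained") net$retained_count else n * (n - 1) / 2
  total / denom
}
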