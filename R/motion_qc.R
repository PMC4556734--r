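#' Framewise displacement
#'
#' Per-frame head-motion magnitude: the sum of absolute backward
#' differences of the three translations (mm) plus the three rotations
#' converted to arc displacement at a `radius` mm sphere.  The leading
#' element is zero so the series has one value per frame.
#'
#' @param realignment `T x 6` matrix: translations (mm) then rotations
#'   (rad).
#' @param radius conversion radius for rotations, mm (default 50).
#' @return numeric vector of length T, non-negative.
#' @export
framewise_displacement <- function(realignment, radius = 50) {
  rp <- as.matrix(realignment)
  if (ncol(rp) != 6)
    stop("realignment must have 6 columns (3 translations, 3 rotations)")
  if (nrow(rp) < 2) stop("need at least 2 frames")
  d <- abs(diff(rp))
  c(0, rowSums(d[, 1:3, drop = FALSE]) +
       radius * rowSums(d[, 4:6, drop = FALSE]))
}

#' Per-subject motion summary
#'
#' `mean_fd` is framewise displacement averaged over the `T - 1` frame
#' transitions; `max_fd` is its maximum; `max_spike` is the largest absolute
#' single-parameter change between consecutive frames, with rotations
#' converted at the same radius.
#'
#' @inheritParams framewise_displacement
#' @return list with `mean_fd`, `max_fd`, `max_spike` (all mm).
#' @export
motion_summary <- function(realignment, radius = 50) {
  rp <- as.matrix(realignment)
  fd <- framewise_displacement(rp, radius)
  d <- abs(diff(rp))
  d[, 4:6] <- d[, 4:6] * radius
  list(mean_fd = mean(fd[-1]), max_fd = max(fd), max_spike = max(d))
}

#' Edgewise FC--motion correlation
#'
#' For every edge, the Pearson correlation across subjects between the
#' edge's functional connectivity and a subject-level motion scalar
#' (typically maximum framewise displacement).
#'
#' @param fc_stack `S x M` matrix: one row per subject, one column per edge
#'   in canonical upper-triangle order.
#' @param motion numeric vector of S motion scalars, non-constant.
#' @return numeric vector of M per-edge correlations.
#' @export
edgewise_motion_correlation <- function(fc_stack, motion) {
  fc_stack <- as.matrix(fc_stack)
  if (nrow(fc_stack) < 3) stop("need at least 3 subjects")
  if (length(motion) != nrow(fc_stack))
    stop("motion must have one value per subject")
  if (sd(motion) == 0) stop("motion scalar is constant across subjects")
  as.vector(cor(motion, fc_stack))
}

# OLS slope of y on x (both vectors), per mm.
ols_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * y) / sum(xc^2)
}

#' Distance profile of edgewise motion correlations
#'
#' Sorts edges by inter-node Euclidean distance, computes a centred moving
#' average of the per-edge correlations (window `round(window_fraction * M)`
#' edges, minimum 3, shrunk at the boundaries), and fits a straight line
#' through the raw correlations against distance.  A negative slope is the
#' signature of a distance-dependent motion artifact: inflated short-range
#' and deflated long-range connectivity.
#'
#' @param edge_r per-edge correlations (see
#'   [edgewise_motion_correlation()]).
#' @param distances per-edge distances, mm, same order.
#' @param window_fraction moving-average window as a fraction of the edge
#'   count, in (0, 0.5].
#' @return list with `distance` (sorted), `moving_average`, `slope`
#'   (correlation change per metre), `slope_per_mm`, `mean_r`, `window`.
#' @export
distance_profile <- function(edge_r, distances, window_fraction = 0.05) {
  m <- length(edge_r)
  if (m < 3) stop("need at least 3 edges")
  if (length(distances) != m) stop("edge_r and distances lengths differ")
  if (window_fraction <= 0 || window_fraction > 0.5)
    stop("window_fraction must be in (0, 0.5]")
  ord <- order(distances)
  d_s <- distances[ord]
  r_s <- edge_r[ord]
  w <- max(3L, as.integer(round_half_away(window_fraction * m)))
  lo <- pmax(1L, seq_len(m) - (w - 1L) %/% 2L)
  hi <- pmin(m, seq_len(m) + w %/% 2L)
  cs <- c(0, cumsum(r_s))
  ma <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  b <- ols_slope(d_s, r_s)
  list(distance = d_s, moving_average = ma,
       slope = 1000 * b, slope_per_mm = b,
       mean_r = mean(edge_r), window = w)
}

#' Permutation null for motion--connectivity coupling
#'
#' Permutes the subject-to-motion assignment `n_perm` times and recomputes
#' the mean edgewise correlation and the fitted distance slope each time,
#' yielding the distribution expected when motion and connectivity are
#' unrelated.  Two-sided empirical p-values use the add-one estimator
#' `p = (1 + #(|null| >= |observed|)) / (1 + n_perm)`, so the smallest
#' attainable p with 100 permutations is 1/101.
#'
#' @inheritParams edgewise_motion_correlation
#' @param distances per-edge distances, mm.
#' @param n_perm number of permutations (default 100).
#' @param seed integer seed.
#' @return list with `mean_r`, `slope` (per metre), `p_mean`, `p_slope`,
#'   `null_mean`, `null_slope`, `n_perm`.
#' @export
permutation_null <- function(fc_stack, motion, distances, n_perm = 100,
                             seed = 1) {
  fc_stack <- as.matrix(fc_stack)
  if (n_perm < 1) stop("n_perm must be at least 1")
  r_obs <- edgewise_motion_correlation(fc_stack, motion)
  mean_obs <- mean(r_obs)
  slope_obs <- ols_slope(distances, r_obs)

  set.seed(as.integer(seed))
  s <- length(motion)
  perm <- vapply(seq_len(n_perm), function(i) sample(motion), numeric(s))
  cmat <- cor(perm, fc_stack)              # n_perm x M
  null_mean <- rowMeans(cmat)
  dc <- distances - mean(distances)
  null_slope <- as.vector(cmat %*% dc) / sum(dc^2)

  p_mean <- (1 + sum(abs(null_mean) >= abs(mean_obs))) / (1 + n_perm)
  p_slope <- (1 + sum(abs(null_slope) >= abs(slope_obs))) / (1 + n_perm)
  list(mean_r = mean_obs, slope = 1000 * slope_obs,
       p_mean = p_mean, p_slope = p_slope,
       null_mean = null_mean, null_slope = 1000 * null_slope,
       n_perm = n_perm)
}

#' Motion QC for a whole cohort
#'
#' Computes per-subject motion summaries, stacks the unthresholded FC edges
#' across subjects, and runs the distance profile and permutation test
#' against the chosen subject-level motion scalar.
#'
#' @param cohort a `cohort`.
#' @param fc_stack optional precomputed `S x M` FC edge stack; computed
#'   from the raw time series when `NULL`.
#' @param scalar subject-level motion scalar: `"max_fd"` (default),
#'   `"mean_fd"` or `"max_spike"`.
#' @param n_perm permutations for the null (default 100).
#' @param seed integer seed.
#' @param window_fraction moving-average window fraction.
#' @return list with `subjects` (data frame of motion summaries),
#'   `profile` (see [distance_profile()]) and `test` (see
#'   [permutation_null()]).
#' @export
motion_qc <- function(cohort, fc_stack = NULL,
                      scalar = c("max_fd", "mean_fd", "max_spike"),
                      n_perm = 100, seed = 1, window_fraction = 0.05) {
  scalar <- match.arg(scalar)
  stopifnot(inherits(cohort, "cohort"))
  sums <- lapply(cohort$subjects, function(s) motion_summary(s$realignment))
  subj <- data.frame(
    subject_id = vapply(cohort$subjects, `[[`, "", "subject_id"),
    group = vapply(cohort$subjects, `[[`, "", "group"),
    mean_fd = vapply(sums, `[[`, numeric(1), "mean_fd"),
    max_fd = vapply(sums, `[[`, numeric(1), "max_fd"),
    max_spike = vapply(sums, `[[`, numeric(1), "max_spike"))
  if (is.null(fc_stack)) {
    fc_stack <- t(vapply(cohort$subjects,
      function(s) upper_tri_values(correlation_matrix(s$timeseries)),
      numeric(nrow(cohort$parcellation) * (nrow(cohort$parcellation) - 1) / 2)))
  }
  motion <- subj[[scalar]]
  dists <- edge_distances(cohort$parcellation)
  r <- edgewise_motion_correlation(fc_stack, motion)
  list(subjects = subj,
       profile = distance_profile(r, dists, window_fraction),
       test = permutation_null(fc_stack, motion, dists, n_perm, seed),
       scalar = scalar)
}
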