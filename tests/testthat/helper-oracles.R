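# Independent brute-force oracles and small fixture builders.  The oracles
# deliberately share no code with the package implementations: clustering by
# exhaustive triple enumeration, shortest paths by Floyd-Warshall.

net_from_weights <- function(w) {
  w <- as.matrix(w)
  diag(w) <- 0
  k <- sum(w[upper.tri(w)] != 0)
  structure(list(weights = w, density = k / (nrow(w) * (nrow(w) - 1) / 2),
                 retained_count = k),
            class = "weighted_network")
}

random_small_network <- function(n, p_edge = 0.6) {
  w <- matrix(0, n, n)
  ut <- which(upper.tri(w))
  on_e <- ut[runif(length(ut)) < p_edge]
  w[on_e] <- runif(length(on_e), 0.05, 1)
  w <- w + t(w)
  net_from_weights(w)
}

oracle_clustering <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  if (mx == 0) return(0)
  wh <- w / mx
  ci <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    acc <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j != i && h != i && j != h) {
          acc <- acc + (wh[i, j] * wh[i, h] * wh[j, h])^(1 / 3)
        }
      }
    }
    ci[i] <- acc / (k * (k - 1))
  }
  mean(ci)
}

oracle_efficiency <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[w > 0] <- 1 / w[w > 0]
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  inv <- 1 / d
  inv[is.infinite(d)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

ut_vals <- function(m) m[upper.tri(m)]

# FC edge stack (subjects x edges) from the raw time series of a cohort.
cohort_fc_stack <- function(cohort) {
  t(vapply(cohort$subjects,
           function(s) ut_vals(correlation_matrix(s$timeseries)),
           numeric(nrow(cohort$parcellation) *
                     (nrow(cohort$parcellation) - 1) / 2)))
}

cohort_groups <- function(cohort) {
  vapply(cohort$subjects, `[[`, "", "group")
}

cohort_motion <- function(cohort, field = "max_fd") {
  vapply(cohort$subjects,
         function(s) motion_summary(s$realignment)[[field]], numeric(1))
}

# Per-subject whole-brain connectivity after thresholding at 20%.
cohort_mean_connectivity <- function(cohort, density = 0.2) {
  vapply(cohort$subjects, function(s)
    mean_connectivity(proportional_threshold(
      correlation_matrix(s$timeseries), density)), numeric(1))
}
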