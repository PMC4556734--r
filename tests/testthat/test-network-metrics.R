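test_that("node strengths sum incident weights", {
  tri <- matrix(0, 3, 3)
  tri[upper.tri(tri)] <- 1
  tri <- tri + t(tri)
  expect_equal(node_strengths(net_from_weights(tri)), rep(2, 3))

  star <- matrix(0, 4, 4)
  star[1, 2:4] <- 0.5
  star <- star + t(star)
  expect_equal(node_strengths(net_from_weights(star)), c(1.5, 0.5, 0.5, 0.5))
  expect_equal(node_strengths(net_from_weights(matrix(0, 3, 3))), rep(0, 3))
})

test_that("clustering and efficiency match hand-worked small graphs", {
  tri <- matrix(0, 3, 3)
  tri[upper.tri(tri)] <- 1
  tri <- tri + t(tri)
  expect_equal(clustering_coefficient(net_from_weights(tri)), 1)
  expect_equal(global_efficiency(net_from_weights(tri)), 1)

  path <- matrix(0, 4, 4)
  path[1, 2] <- path[2, 3] <- path[3, 4] <- 1
  path <- path + t(path)
  expect_equal(clustering_coefficient(net_from_weights(path)), 0)

  # one weighted triangle {1, 0.5, 0.5} plus a pendant edge
  w4 <- matrix(0, 4, 4)
  w4[1, 2] <- 1; w4[1, 3] <- 0.5; w4[2, 3] <- 0.5; w4[3, 4] <- 0.8
  w4 <- w4 + t(w4)
  expect_equal(clustering_coefficient(net_from_weights(w4)),
               oracle_clustering(w4), tolerance = 1e-12)

  # 3-node path, weights 1 and 0.5: d13 = 1 + 2 = 3
  p3 <- matrix(0, 3, 3)
  p3[1, 2] <- 1; p3[2, 3] <- 0.5
  p3 <- p3 + t(p3)
  expect_equal(global_efficiency(net_from_weights(p3)),
               (1 + 0.5 + 1 / 3) * 2 / 6)

  # two disconnected unit dyads: only within-dyad pairs contribute
  dy <- matrix(0, 4, 4)
  dy[1, 2] <- dy[3, 4] <- 1
  dy <- dy + t(dy)
  expect_equal(global_efficiency(net_from_weights(dy)), 1 / 3)

  expect_error(clustering_coefficient(net_from_weights(-tri)), "negative")
  expect_error(global_efficiency(net_from_weights(-tri)), "negative")
})

test_that("weighted shortest paths beat direct edges when detours are stronger", {
  # direct weak edge (length 10) vs two strong hops (length 2 + 2)
  w <- matrix(0, 3, 3)
  w[1, 3] <- 0.1; w[1, 2] <- 0.5; w[2, 3] <- 0.5
  w <- w + t(w)
  expect_equal(global_efficiency(net_from_weights(w)),
               oracle_efficiency(w), tolerance = 1e-12)
})

test_that("null networks preserve degree sequence and weight multiset", {
  set.seed(6)
  fc <- correlation_matrix(matrix(rnorm(80 * 15), 80, 15))
  net <- proportional_threshold(fc, 0.3)
  ens <- null_ensemble(net, n = 8, seed = 3)
  orig_deg <- rowSums(net$weights > 0)
  orig_w <- sort(ut_vals(net$weights)[ut_vals(net$weights) != 0])
  for (nn in ens) {
    expect_equal(rowSums(nn$weights > 0), orig_deg)
    expect_equal(sort(ut_vals(nn$weights)[ut_vals(nn$weights) != 0]), orig_w)
    expect_equal(nn$retained_count, net$retained_count)
    expect_equal(sum(nn$weights), sum(net$weights))
    expect_equal(nn$weights, t(nn$weights))
  }
  # deterministic per seed
  expect_identical(null_ensemble(net, n = 2, seed = 5),
                   null_ensemble(net, n = 2, seed = 5))
})

test_that("a rigid triangle topology can only permute its weights", {
  tri <- matrix(0, 3, 3)
  tri[1, 2] <- 0.9; tri[1, 3] <- 0.5; tri[2, 3] <- 0.2
  tri <- tri + t(tri)
  ens <- null_ensemble(net_from_weights(tri), n = 5, seed = 1)
  for (nn in ens) {
    expect_equal(sort(ut_vals(nn$weights)), c(0.2, 0.5, 0.9))
    expect_equal(rowSums(nn$weights > 0), rep(2, 3))
  }
})

test_that("metric normalisation divides by the null-ensemble mean", {
  set.seed(7)
  fc <- correlation_matrix(matrix(rnorm(60 * 12), 60, 12))
  net <- proportional_threshold(fc, 0.3)
  ens <- null_ensemble(net, n = 10, seed = 2)
  res <- normalize_metric(clustering_coefficient, net, ens)
  expect_equal(res$normalized, res$raw / res$null_mean)
  expect_equal(res$ensemble_size, 10)
  # constant metric and self-ensemble both give exactly 1
  expect_equal(normalize_metric(function(x) 42, net, ens)$normalized, 1)
  expect_equal(normalize_metric(clustering_coefficient, net,
                                list(net))$normalized, 1)
  # a weighted ring lattice is more clustered than its rewired nulls
  n <- 24
  ring <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (d in 1:2) {
      j <- ((i + d - 1) %% n) + 1
      ring[i, j] <- ring[j, i] <- 1 / d
    }
  }
  ringnet <- net_from_weights(ring)
  cnorm <- normalize_metric(clustering_coefficient, ringnet,
                            null_ensemble(ringnet, n = 10, seed = 4))
  expect_gt(cnorm$normalized, 1)
})

test_that("node disruption index obeys its algebraic identities", {
  set.seed(8)
  s <- runif(50, 1, 10)
  expect_equal(node_disruption_index(s, s)$slope, 0, tolerance = 1e-12)
  expect_equal(node_disruption_index(s + 2.5, s)$intercept, 2.5)
  expect_equal(node_disruption_index(s + 2.5, s)$slope, 0, tolerance = 1e-12)
  for (k in c(0.5, 0.8, 1.2)) {
    expect_equal(node_disruption_index(k * s, s)$slope, k - 1,
                 tolerance = 1e-12)
  }
  expect_error(node_disruption_index(s, rep(1, 50)), "degenerate")
  expect_error(node_disruption_index(s, s[-1]), "equal length")
})

test_that("group templates average strengths, optionally leave-one-out", {
  s <- rbind(c(1, 2, 3), c(3, 6, 9))
  expect_equal(group_template(s), c(2, 4, 6))
  s3 <- rbind(a = c(1, 1), b = c(2, 2), c = c(6, 6))
  loo <- group_template(s3, leave_one_out = TRUE)
  expect_equal(loo[1, ], c(4, 4))
  expect_equal(loo[3, ], c(1.5, 1.5))
  expect_error(group_template(s[1, , drop = FALSE]), "at least 2")
})

test_that("hub selection takes the top strength fraction with stable ties", {
  parc <- generate_parcellation(10, 2, seed = 9)
  hp <- identify_hubs(seq(0.1, 1, by = 0.1), parc, fraction = 0.2)
  expect_equal(sort(hp$hub_set), sort(parc$node_id[9:10]))

  parc258 <- load_packaged_parcellation()
  set.seed(10)
  hp258 <- identify_hubs(runif(258), parc258, fraction = 0.2)
  expect_equal(length(hp258$hub_set), 52L)   # round(0.2 * 258)
  expect_equal(sum(hp258$counts) +
                 sum(!parc258$analyzed[match(hp258$hub_set, parc258$node_id)]),
               52L)

  # hub fraction bound
  for (n in c(10, 37, 258)) {
    frac <- 0.2
    k <- length(identify_hubs(runif(n), generate_parcellation(n, 2, seed = n),
                              fraction = frac)$hub_set)
    expect_gte(k / n, frac - 1 / n)
    expect_lte(k / n, frac + 1 / n)
  }

  # ties broken by node id ascending
  parc4 <- generate_parcellation(4, 2, seed = 1)
  tied <- identify_hubs(rep(1, 4), parc4, fraction = 0.5)
  expect_equal(tied$hub_set, parc4$node_id[1:2])
})

test_that("block weights separate intra- from inter-network connectivity", {
  parc <- generate_parcellation(8, 2, seed = 11)
  idx_a <- which(parc$network == parc$network[1])
  w <- matrix(0, 8, 8)
  w[idx_a[1], idx_a[2]] <- 0.9           # intra edge in network A
  w <- w + t(w)
  bw <- network_block_weights(net_from_weights(w), parc)
  row_a <- bw[bw$network == parc$network[1], ]
  expect_equal(row_a$inter, 0)
  expect_gt(row_a$intra, 0)

  # uniform weights: intra = inter = w everywhere
  u <- matrix(0.4, 8, 8)
  diag(u) <- 0
  bu <- network_block_weights(net_from_weights(u), parc)
  expect_equal(bu$intra, rep(0.4, nrow(bu)))
  expect_equal(bu$inter, rep(0.4, nrow(bu)))

  # single cross edge of 0.6 between 2+2 networks: inter mean = 0.6 / 4
  parc4 <- generate_parcellation(4, 2, seed = 1)
  a_nodes <- which(parc4$network == parc4$network[1])
  b_nodes <- setdiff(1:4, a_nodes)
  x <- matrix(0, 4, 4)
  x[a_nodes[1], b_nodes[1]] <- 0.6
  x <- x + t(x)
  bx <- network_block_weights(net_from_weights(x), parc4)
  expect_equal(bx$inter, rep(0.6 / 4, 2))
})

test_that("group-mean NDI recovers the hypoconnectivity gradient in expectation", {
  # expectation over 20 seeded full-scale cohorts: control template, so
  # mean NDI is 0 > SIB > ASC; individual cohorts are noisier than the
  # whole-brain connectivity gradient because NDI measures profile shape,
  # not total connectivity
  parc <- load_packaged_parcellation()
  n <- nrow(parc)
  ndi_mat <- matrix(NA_real_, 20, 2, dimnames = list(NULL, c("SIB", "ASC")))
  for (s in seq_len(20)) {
    d <- cohort_design(n_per_group = 14, n_timepoints = 300, seed = 300 + s)
    co <- generate_cohort(parc, d)
    grp <- cohort_groups(co)
    strengths <- t(vapply(co$subjects, function(x)
      node_strengths(proportional_threshold(
        correlation_matrix(x$timeseries), 0.2)), numeric(n)))
    tmpl <- group_template(strengths[grp == "CON", ])
    ndi <- vapply(seq_along(grp), function(i)
      node_disruption_index(strengths[i, ], tmpl)$slope, numeric(1))
    ndi_mat[s, ] <- tapply(ndi, grp, mean)[c("SIB", "ASC")]
  }
  avg <- colMeans(ndi_mat)
  expect_lt(avg["SIB"], 0)
  expect_lt(avg["ASC"], avg["SIB"])
})
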