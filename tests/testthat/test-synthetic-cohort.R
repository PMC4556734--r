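test_that("parcellation generation partitions nodes into near-equal networks", {
  parc <- generate_parcellation(258, 14, seed = 1)
  expect_equal(nrow(parc), 258)
  expect_equal(length(unique(parc$node_id)), 258)
  sizes <- table(parc$network)
  expect_equal(length(sizes), 14L)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_equal(sum(parc$analyzed),
               sum(parc$network %in% analyzed_network_names()))

  small <- generate_parcellation(4, 2, seed = 7)
  expect_equal(sort(small$node_id), 0:3)
  expect_equal(as.integer(sort(table(small$network))), c(2L, 2L))

  # centroids inside the brain-scale ellipsoid
  expect_true(all((parc$x / 70)^2 + (parc$y / 85)^2 + (parc$z / 60)^2 <= 1))
})

test_that("parcellation and cohort generation are deterministic per seed", {
  expect_identical(generate_parcellation(258, 14, seed = 1),
                   generate_parcellation(258, 14, seed = 1))
  parc <- generate_parcellation(20, 4, seed = 3)
  d <- cohort_design(n_per_group = 2, n_timepoints = 60, seed = 11)
  expect_identical(generate_cohort(parc, d), generate_cohort(parc, d))
  # different seed changes the draw
  d2 <- d
  d2$seed <- 12
  expect_false(identical(generate_cohort(parc, d)$subjects[[1]]$timeseries,
                         generate_cohort(parc, d2)$subjects[[1]]$timeseries))
})

test_that("generation rejects invalid arguments", {
  expect_error(generate_parcellation(0, 2), "positive")
  expect_error(generate_parcellation(3, 5), "at least")
  expect_error(generate_motion_trace(1), "at least 2")
  expect_error(motion_design(spike_rate = 1.5), "spike_rate")
  expect_error(cohort_design(n_per_group = 1), "at least 2")
  expect_error(cohort_design(global_coupling = c(CON = 1, SIB = 1)), "ASC")
})

test_that("motion traces follow the walk-plus-spike model", {
  still <- generate_motion_trace(50, motion_design(walk_sd_trans = 0,
    walk_sd_rot = 0, spike_rate = 0, subject_scale_sd = 0), seed = 1)
  expect_true(all(still == 0))
  expect_true(all(framewise_displacement(still) == 0))

  spiky <- generate_motion_trace(50, motion_design(walk_sd_trans = 0,
    walk_sd_rot = 0, spike_rate = 1, spike_scale = 0.3), seed = 2)
  steps <- abs(diff(spiky))
  expect_true(all(apply(steps, 1, max) >= 0.3 - 1e-9))

  # default walk: realistic adolescent-scale motion
  tr <- generate_motion_trace(200, motion_design(), seed = 3)
  mfd <- motion_summary(tr)$mean_fd
  expect_gt(mfd, 0.01)
  expect_lt(mfd, 1.0)
})

test_that("factor-model correlations match the closed form", {
  # noiseless limit, no confounds: same-network r -> 1,
  # cross-network r -> g^2 / (g^2 + w^2)
  parc <- generate_parcellation(12, 3, seed = 4)
  g <- 0.6
  w <- 0.4
  d <- cohort_design(n_per_group = 2,
                     global_coupling = c(CON = g, SIB = g, ASC = g),
                     within_network_loading = w, noise_sd = 1e-6,
                     n_timepoints = 2000, confound_loading_sd = 0,
                     motion = motion_design(artifact_gain = 0), seed = 8)
  co <- generate_cohort(parc, d)
  fc <- correlation_matrix(co$subjects[[1]]$timeseries)
  same <- outer(parc$network, parc$network, "==") & upper.tri(fc)
  diff_net <- !outer(parc$network, parc$network, "==") & upper.tri(fc)
  expected <- g^2 / (g^2 + w^2)
  # band-limiting to 0.01-0.1 Hz leaves ~36% of the Nyquist band, so the
  # effective sample count is ~0.36 * T; allow 3 standard errors
  se <- (1 - expected^2) / sqrt(0.36 * 2000)
  expect_equal(mean(fc[same]), 1, tolerance = 1e-3)
  expect_lt(abs(mean(fc[diff_net]) - expected), 3 * se)
})

test_that("independent-noise cohorts have near-zero off-diagonal correlation", {
  parc <- generate_parcellation(10, 2, seed = 5)
  d <- cohort_design(n_per_group = 2,
                     global_coupling = c(CON = 0, SIB = 0, ASC = 0),
                     within_network_loading = 0, confound_loading_sd = 0,
                     n_timepoints = 1500,
                     motion = motion_design(artifact_gain = 0), seed = 9)
  co <- generate_cohort(parc, d)
  fc <- correlation_matrix(co$subjects[[1]]$timeseries)
  expect_lt(mean(abs(ut_vals(fc))), 3 / sqrt(1500))
})

test_that("expected global connectivity increases with the group coupling", {
  parc <- generate_parcellation(20, 4, seed = 6)
  mean_by_group <- matrix(NA_real_, 20, 3,
                          dimnames = list(NULL, c("CON", "SIB", "ASC")))
  for (s in seq_len(20)) {
    d <- cohort_design(n_per_group = 3, n_timepoints = 300, seed = 100 + s)
    co <- generate_cohort(parc, d)
    mc <- cohort_mean_connectivity(co)
    grp <- cohort_groups(co)
    mean_by_group[s, ] <- tapply(mc, grp, mean)[c("CON", "SIB", "ASC")]
  }
  avg <- colMeans(mean_by_group)
  expect_gt(avg["CON"], avg["SIB"])
  expect_gt(avg["SIB"], avg["ASC"])
})

test_that("motion artifact couples connectivity to framewise displacement", {
  parc <- generate_parcellation(30, 10, seed = 9)
  fdfc <- numeric(3)
  for (s in 1:3) {
    d <- cohort_design(n_per_group = 14, n_timepoints = 200, seed = 200 + s,
                       motion = motion_design(artifact_gain = 5))
    co <- generate_cohort(parc, d)
    mean_fd <- vapply(co$subjects, function(x) mean(x$truth$fd), numeric(1))
    mean_fc <- rowMeans(cohort_fc_stack(co))
    fdfc[s] <- cor(mean_fd, mean_fc)
  }
  expect_true(all(fdfc > 0))
})

test_that("band-limited factors have unit variance and stay in band", {
  set.seed(42)
  x <- band_limited_series(400, 2, 0.01, 0.1, n_series = 3)
  expect_equal(apply(x, 2, sd), rep(1, 3))
  spec <- Mod(mvfft(x))^2
  freq <- c(0:200, 199:1) / (400 * 2)
  out_of_band <- freq < 0.01 | freq > 0.1
  expect_lt(max(spec[out_of_band, ]), 1e-16)
})
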