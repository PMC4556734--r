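#' Motion simulation design
#'
#' Parameters of the simulated rigid-body realignment traces and of the
#' optional motion artifact injected into the time series.
#'
#' Realignment traces are cumulative Gaussian random walks (3 translations
#' in mm, 3 rotations in rad) with occasional persistent repositioning
#' "spikes": at each timepoint, with probability `spike_rate`, one randomly
#' chosen translation parameter jumps by `spike_scale` mm (random sign) and
#' stays there, as heads do.  When `artifact_gain > 0`, a shared signal
#' proportional to framewise displacement is injected into the node time
#' series with inter-node sharing that decays as
#' `exp(-distance / artifact_distance_scale)`.
#'
#' @param walk_sd_trans random-walk step sd for translations, mm.
#' @param walk_sd_rot random-walk step sd for rotations, rad.
#' @param spike_rate per-timepoint probability of a repositioning spike.
#' @param spike_scale spike magnitude, mm.
#' @param artifact_gain coupling of framewise displacement to the injected
#'   shared signal; 0 (default) yields motion-independent data.
#' @param artifact_distance_scale decay constant of artifact sharing with
#'   inter-node distance, mm.
#' @param artifact_profile_mean mean of the artifact spatial profile; a
#'   positive mean makes motion shift connectivity predominantly upward
#'   (movers show higher FC), on top of the distance-decaying shared part.
#' @param subject_scale_sd sd of the per-subject lognormal motion
#'   multiplier applied by [generate_cohort()] to walk and spike
#'   magnitudes, emulating the usual cohort of mostly low movers with a few
#'   big movers; 0 makes every subject move alike.
#' @return a `motion_design` list.
#' @export
motion_design <- function(walk_sd_trans = 0.02, walk_sd_rot = 2e-4,
                          spike_rate = 0.02, spike_scale = 0.5,
                          artifact_gain = 0, artifact_distance_scale = 50,
                          artifact_profile_mean = 1, subject_scale_sd = 0.5) {
  if (spike_rate < 0 || spike_rate > 1) stop("spike_rate must be in [0, 1]")
  if (any(c(walk_sd_trans, walk_sd_rot, spike_scale, artifact_gain,
            artifact_distance_scale, subject_scale_sd) < 0))
    stop("motion design scales must be non-negative")
  structure(list(walk_sd_trans = walk_sd_trans, walk_sd_rot = walk_sd_rot,
                 spike_rate = spike_rate, spike_scale = spike_scale,
                 artifact_gain = artifact_gain,
                 artifact_distance_scale = artifact_distance_scale,
                 artifact_profile_mean = artifact_profile_mean,
                 subject_scale_sd = subject_scale_sd),
            class = "motion_design")
}

#' Simulate a realignment trace
#'
#' Cumulative random walk over the six rigid-body parameters with persistent
#' Bernoulli repositioning spikes (see [motion_design()]).  The first row is
#' zero; columns are `trans_x`, `trans_y`, `trans_z` (mm) then `rot_x`,
#' `rot_y`, `rot_z` (rad).
#'
#' @param n_timepoints number of frames, at least 2.
#' @param design a [motion_design()].
#' @param seed integer seed, or `NULL` to draw from the current RNG stream
#'   (used when a caller manages seeding for a whole cohort).
#' @return `n_timepoints` x 6 numeric matrix.
#' @export
generate_motion_trace <- function(n_timepoints, design = motion_design(),
                                  seed = NULL) {
  if (n_timepoints < 2)
    stop("n_timepoints must be at least 2 (no frame-to-frame derivative otherwise)")
  if (!is.null(seed)) set.seed(as.integer(seed))
  tt <- n_timepoints
  sds <- rep(c(design$walk_sd_trans, design$walk_sd_rot), each = 3)
  steps <- matrix(0, tt, 6)
  for (p in 1:6) steps[2:tt, p] <- rnorm(tt - 1, 0, sds[p])
  if (design$spike_rate > 0 && design$spike_scale > 0) {
    hit <- which(runif(tt - 1) < design$spike_rate) + 1L
    for (t0 in hit) {
      p <- sample.int(3, 1)              # translation parameter
      steps[t0, p] <- steps[t0, p] +
        sample(c(-1, 1), 1) * design$spike_scale
    }
  }
  trace <- apply(steps, 2, cumsum)
  colnames(trace) <- c("trans_x", "trans_y", "trans_z",
                       "rot_x", "rot_y", "rot_z")
  trace
}

#' Cohort simulation design
#'
#' Statistical design of a synthetic three-group cohort.  Each subject's
#' node time series follows a factor model: a global factor loaded by the
#' subject's group coupling `g`, one factor per functional network loaded by
#' `within_network_loading`, two nuisance signals (CSF-like and WM-like)
#' with known per-node loadings, i.i.d. Gaussian noise, and an optional
#' motion artifact.  All factors are unit-variance Gaussian series
#' band-limited to 0.01--0.1 Hz at the configured sampling interval, so the
#' preprocessing band-pass is non-destructive for signal.
#'
#' The default coupling gradient `CON > SIB > ASC` encodes the
#' hypoconnectivity-endophenotype structure the analysis is designed to
#' detect: controls strongest, autistic participants weakest, siblings
#' intermediate.
#'
#' @param n_per_group subjects per group (default 14, at least 2).
#' @param groups ordered group labels.
#' @param global_coupling named map group -> global-factor loading `g >= 0`.
#' @param within_network_loading loading of each network factor.
#' @param noise_sd sd of the i.i.d. Gaussian noise (> 0).
#' @param n_timepoints frames per scan (default 300).
#' @param sampling_interval seconds per frame (default 2).
#' @param motion a [motion_design()].
#' @param confound_loading_sd sd of the (half-normal) per-node loadings of
#'   the two nuisance signals.
#' @param condition condition label attached to every subject.
#' @param seed master integer seed for the cohort.
#' @return a `cohort_design` list.
#' @export
cohort_design <- function(n_per_group = 14,
                          groups = c("CON", "SIB", "ASC"),
                          global_coupling = c(CON = 0.8, SIB = 0.6, ASC = 0.4),
                          within_network_loading = 0.4,
                          noise_sd = 1,
                          n_timepoints = 300,
                          sampling_interval = 2,
                          motion = motion_design(),
                          confound_loading_sd = 0.2,
                          condition = "rest",
                          seed = 1) {
  if (n_per_group < 2) stop("n_per_group must be at least 2")
  if (sampling_interval <= 0) stop("sampling_interval must be positive")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (!all(groups %in% names(global_coupling)))
    stop("global_coupling must name every group: ",
         paste(setdiff(groups, names(global_coupling)), collapse = ", "))
  if (any(!is.finite(global_coupling)) || any(global_coupling < 0))
    stop("global_coupling loadings must be finite and non-negative")
  if (!is.finite(within_network_loading) || within_network_loading < 0)
    stop("within_network_loading must be finite and non-negative")
  structure(list(n_per_group = n_per_group, groups = groups,
                 global_coupling = global_coupling,
                 within_network_loading = within_network_loading,
                 noise_sd = noise_sd, n_timepoints = n_timepoints,
                 sampling_interval = sampling_interval, motion = motion,
                 confound_loading_sd = confound_loading_sd,
                 condition = condition, seed = seed),
            class = "cohort_design")
}

#' Band-limited unit-variance Gaussian series
#'
#' White Gaussian noise restricted to a frequency band by discrete Fourier
#' masking and rescaled to unit sample variance per column.  These are the
#' latent factors of the cohort model.
#'
#' @param n length of each series.
#' @param dt sampling interval, seconds.
#' @param low_hz,high_hz passband edges (defaults 0.01 and 0.1 Hz).
#' @param n_series number of independent columns.
#' @return `n` x `n_series` matrix.
#' @export
band_limited_series <- function(n, dt, low_hz = 0.01, high_hz = 0.1,
                                n_series = 1) {
  freq <- dft_frequencies(n, dt)
  keep <- freq >= low_hz & freq <= high_hz & freq > 0
  if (!any(keep))
    stop("no DFT bins inside the requested band; series too short")
  x <- matrix(rnorm(n * n_series), n, n_series)
  xf <- mvfft(x)
  xf[!keep, ] <- 0
  y <- Re(mvfft(xf, inverse = TRUE)) / n
  y <- sweep(y, 2, colMeans(y))
  sweep(y, 2, apply(y, 2, sd), "/")
}

#' Generate a synthetic cohort
#'
#' Simulates one subject record per group member under the factor model of
#' [cohort_design()].  Per subject the `T x N` time series is
#' `g * global + w * network_factor + confound loadings * (CSF, WM) + noise`,
#' plus, when `artifact_gain > 0`, a motion artifact
#' `gain * FD(t) * w_node`, where the static spatial profile `w_node` is
#' drawn from a Gaussian process with covariance
#' `exp(-distance / artifact_distance_scale)` so that artifact sharing
#' decays with inter-node distance.
#'
#' Identical seeds and designs yield bit-identical cohorts.
#'
#' @param parc a `parcellation` defining the nodes and networks.
#' @param design a [cohort_design()].
#' @return a `cohort`: list with `subjects` (list of `subject_record`),
#'   `parcellation`, `design`.  Each subject record carries `subject_id`,
#'   `group`, `condition`, `timeseries` (T x N), `realignment` (T x 6),
#'   `confounds` (T x 2, the observed CSF/WM-like means) and `truth` (the
#'   generating parameters, for recovery tests).
#' @export
generate_cohort <- function(parc, design = cohort_design()) {
  stopifnot(inherits(parc, "parcellation") || is.data.frame(parc))
  n_nodes <- nrow(parc)
  nets <- factor(parc$network)
  net_idx <- as.integer(nets)
  n_networks <- nlevels(nets)
  tt <- design$n_timepoints
  dt <- design$sampling_interval

  set.seed(as.integer(design$seed))
  conf_load <- matrix(abs(rnorm(2 * n_nodes, 0, design$confound_loading_sd)),
                      n_nodes, 2)

  art <- design$motion$artifact_gain > 0
  chol_k <- NULL
  if (art) {
    k <- exp(-centroid_distances(parc) / design$motion$artifact_distance_scale)
    chol_k <- chol(k + diag(1e-8, n_nodes))
  }

  groups <- rep(design$groups, each = design$n_per_group)
  subjects <- vector("list", length(groups))
  for (s in seq_along(groups)) {
    grp <- groups[s]
    g <- design$global_coupling[[grp]]
    w <- design$within_network_loading
    fac <- band_limited_series(tt, dt, n_series = n_networks + 3)
    global <- fac[, 1]
    netfac <- fac[, 1 + seq_len(n_networks), drop = FALSE]
    csf <- fac[, n_networks + 2]
    wm <- fac[, n_networks + 3]

    ts <- g * matrix(global, tt, n_nodes) +
      w * netfac[, net_idx, drop = FALSE] +
      csf %*% t(conf_load[, 1]) + wm %*% t(conf_load[, 2]) +
      design$noise_sd * matrix(rnorm(tt * n_nodes), tt, n_nodes)

    mo <- design$motion
    if (mo$subject_scale_sd > 0) {
      mscale <- exp(rnorm(1, 0, mo$subject_scale_sd))
      mo$walk_sd_trans <- mo$walk_sd_trans * mscale
      mo$walk_sd_rot <- mo$walk_sd_rot * mscale
      mo$spike_scale <- mo$spike_scale * mscale
    }
    rp <- generate_motion_trace(tt, mo, seed = NULL)
    fd <- framewise_displacement(rp)
    profile <- NULL
    if (art) {
      profile <- design$motion$artifact_profile_mean +
        drop(crossprod(chol_k, rnorm(n_nodes)))
      ts <- ts + design$motion$artifact_gain * (fd %*% t(profile))
    }

    subjects[[s]] <- structure(list(
      subject_id = sprintf("sub-%s-%02d", grp,
                           ((s - 1) %% design$n_per_group) + 1L),
      group = grp,
      condition = design$condition,
      timeseries = ts,
      realignment = rp,
      confounds = cbind(csf = csf, wm = wm),
      truth = list(g = g, within_network_loading = w,
                   confound_loadings = conf_load,
                   confound_signals = cbind(csf = csf, wm = wm),
                   artifact_profile = profile, fd = fd)),
      class = "subject_record")
  }
  structure(list(subjects = subjects, parcellation = parc, design = design),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  grp <- table(vapply(x$subjects, `[[`, "", "group"))
  cat(sprintf("synthetic cohort: %d subjects (%s), %d nodes, T = %d, condition '%s'\n",
              length(x$subjects),
              paste(sprintf("%s n=%d", names(grp), grp), collapse = ", "),
              nrow(x$parcellation), x$design$n_timepoints,
              x$design$condition))
  invisible(x)
}
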