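# Frequency (Hz) of each DFT bin for a length-n series sampled every dt
# seconds; bin k and its mirror share the same physical frequency.
dft_frequencies <- function(n, dt) {
  k <- 0:(n - 1)
  k <- pmin(k, n - k)
  k / (n * dt)
}

#' Band-pass filter specification
#'
#' The analysis band of the pipeline: a 0.01 Hz high-pass and an optional
#' 0.1 Hz low-pass, realised as an ideal (zero-phase) discrete-Fourier
#' mask.  `lowpass_hz = NULL` disables the low-pass, giving the
#' "task-evoked" variant of the pipeline.
#'
#' @param highpass_hz high-pass edge, Hz (> 0).
#' @param lowpass_hz low-pass edge, Hz, or `NULL` to disable.
#' @param sampling_interval seconds per frame.
#' @param despike clip large excursions before filtering (see
#'   [despike_timeseries()]).
#' @return a `filter_spec` list.
#' @export
filter_spec <- function(highpass_hz = 0.01, lowpass_hz = 0.1,
                        sampling_interval = 2, despike = FALSE) {
  if (sampling_interval <= 0) stop("sampling_interval must be positive")
  nyquist <- 1 / (2 * sampling_interval)
  if (highpass_hz <= 0) stop("highpass_hz must be positive")
  if (!is.null(lowpass_hz)) {
    if (lowpass_hz >= nyquist)
      stop(sprintf("lowpass_hz (%g) must be below the Nyquist frequency (%g Hz)",
                   lowpass_hz, nyquist))
    if (highpass_hz >= lowpass_hz)
      stop("highpass_hz must be below lowpass_hz")
  }
  structure(list(highpass_hz = highpass_hz, lowpass_hz = lowpass_hz,
                 sampling_interval = sampling_interval,
                 despike = isTRUE(despike)),
            class = "filter_spec")
}

#' Expand nuisance regressors
#'
#' Expands a `T x K` matrix of base nuisance series (canonically the 6
#' realignment parameters plus CSF and WM mean signals, K = 8) into the
#' `T x 4K` confound set: base, backward-difference derivatives (first row
#' zero), squares of the base, and squares of the derivatives.  With K = 8
#' this yields the standard 32-regressor confound model.
#'
#' @param base `T x K` numeric matrix, `T >= 3`.
#' @return `T x 4K` matrix with suffixed column names.
#' @export
expand_confounds <- function(base) {
  base <- as.matrix(base)
  if (nrow(base) < 3) stop("need at least 3 timepoints to expand confounds")
  d <- rbind(0, diff(base))
  out <- cbind(base, d, base^2, d^2)
  nm <- colnames(base) %||% sprintf("c%d", seq_len(ncol(base)))
  colnames(out) <- c(nm, paste0(nm, "_deriv"), paste0(nm, "_sq"),
                     paste0(nm, "_deriv_sq"))
  out
}

#' Regress confounds out of node time series
#'
#' Least-squares projection of each node series onto the orthogonal
#' complement of the confound columns (an intercept is always included).
#' Constant columns (absorbed by the intercept) and exact duplicates are
#' dropped before fitting; if the remaining design is still rank deficient,
#' the offending columns are reported as an error.
#'
#' @param ts `T x N` time-series matrix.
#' @param confounds `T x M` confound matrix, `M < T`.
#' @return `T x N` residual matrix; the columns actually regressed are
#'   recorded in the `"confounds_used"` attribute.
#' @export
regress_confounds <- function(ts, confounds) {
  ts <- as.matrix(ts)
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != nrow(ts))
    stop("time series and confounds must share the number of timepoints")
  if (ncol(confounds) >= nrow(ts))
    stop("more confounds than timepoints; regression is undetermined")
  cn <- colnames(confounds) %||% sprintf("c%d", seq_len(ncol(confounds)))
  colnames(confounds) <- cn

  keep <- apply(confounds, 2, function(x) sd(x) > 0)
  x <- confounds[, keep, drop = FALSE]
  x <- x[, !duplicated(t(x)), drop = FALSE]

  design <- cbind(intercept = 1, x)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    bad <- colnames(design)[qr_d$pivot[(qr_d$rank + 1):ncol(design)]]
    stop("confound matrix is rank deficient after de-duplication; ",
         "collinear columns: ", paste(bad, collapse = ", "))
  }
  res <- ts - design %*% qr.coef(qr_d, ts)
  attr(res, "confounds_used") <- colnames(design)[-1]
  res
}

#' Clip spikes with a running-median / MAD rule
#'
#' Per node, values whose deviation from the running median (window 7)
#' exceeds `n_mads` median-absolute-deviations of those deviations are
#' shrunk to that bound.  A simple, testable despiking rule applied before
#' filtering when `filter_spec(despike = TRUE)`.
#'
#' @param ts `T x N` matrix.
#' @param window running-median window (odd, default 7).
#' @param n_mads clipping threshold in MAD units (default 4).
#' @return despiked `T x N` matrix.
#' @export
despike_timeseries <- function(ts, window = 7, n_mads = 4) {
  ts <- as.matrix(ts)
  apply(ts, 2, function(x) {
    med <- runmed(x, window, endrule = "median")
    resid <- x - med
    # the running median reproduces smooth series exactly at most points,
    # so the MAD of the deviations can degenerate to zero; fall back to the
    # (less robust) standard deviation there
    s <- mad(resid)
    if (s == 0) s <- sd(resid)
    if (s == 0) return(x)
    bound <- n_mads * s
    med + pmin(pmax(resid, -bound), bound)
  })
}

#' Ideal band-pass filter
#'
#' Zero-phase frequency-domain masking: DFT bins with frequency below the
#' high-pass edge (including the mean) or above the low-pass edge are
#' zeroed.  If the spec requests despiking, [despike_timeseries()] runs
#' first.  The ideal mask is linear and idempotent.
#'
#' @param ts `T x N` matrix, `T >= 16`.
#' @param spec a [filter_spec()].
#' @return filtered `T x N` matrix.
#' @export
bandpass_filter <- function(ts, spec = filter_spec()) {
  ts <- as.matrix(ts)
  tt <- nrow(ts)
  if (tt < 16) stop("need at least 16 timepoints to band-pass filter")
  if (!inherits(spec, "filter_spec")) stop("spec must be a filter_spec")
  if (spec$despike) ts <- despike_timeseries(ts)
  freq <- dft_frequencies(tt, spec$sampling_interval)
  keep <- freq >= spec$highpass_hz
  if (!is.null(spec$lowpass_hz)) keep <- keep & freq <= spec$lowpass_hz
  xf <- mvfft(ts)
  xf[!keep, ] <- 0
  out <- Re(mvfft(xf, inverse = TRUE)) / tt
  dimnames(out) <- dimnames(ts)
  out
}

#' Preprocess one subject record
#'
#' The time-series stage of the pipeline in one pass: optional despiking,
#' regression of the expanded confound set (realignment 6 + CSF + WM ->
#' 32 regressors), then band-pass filtering.  Regression precedes filtering
#' so filtered-band confound energy is not reintroduced.
#'
#' @param record a `subject_record` (see [generate_cohort()]).
#' @param spec a [filter_spec()].
#' @return the record with `timeseries` replaced by its preprocessed
#'   version and `preprocessed = TRUE`.
#' @export
preprocess_subject <- function(record, spec = filter_spec()) {
  stopifnot(inherits(record, "subject_record"))
  base <- cbind(record$realignment, record$confounds)
  ts <- record$timeseries
  if (spec$despike) ts <- despike_timeseries(ts)
  ts <- regress_confounds(ts, expand_confounds(base))
  spec_nospike <- spec
  spec_nospike$despike <- FALSE
  record$timeseries <- bandpass_filter(ts, spec_nospike)
  record$preprocessed <- TRUE
  record
}

#' @rdname preprocess_subject
#' @param cohort a `cohort`.
#' @export
preprocess_cohort <- function(cohort, spec = filter_spec()) {
  stopifnot(inherits(cohort, "cohort"))
  cohort$subjects <- lapply(cohort$subjects, preprocess_subject, spec = spec)
  cohort$filter <- spec
  cohort
}
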