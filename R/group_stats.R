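#' One-way fixed-effects ANOVA
#'
#' Classical one-way ANOVA on a named list of per-group value vectors:
#' `F = MSB / MSW` on `(k - 1, N - k)` degrees of freedom.
#'
#' @param sample named list mapping group label to a numeric vector with at
#'   least 2 values.
#' @return an `anova_result`: `F`, `df_between`, `df_within`, `p`.
#' @examples
#' oneway_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(5, 6, 7)))
#' @export
oneway_anova <- function(sample) {
  if (!is.list(sample) || length(sample) < 2)
    stop("need at least 2 groups")
  ns <- lengths(sample)
  if (any(ns < 2)) stop("every group needs at least 2 subjects")
  values <- unlist(sample, use.names = FALSE)
  if (any(!is.finite(values))) stop("group values must be finite")
  grp <- factor(rep(names(sample) %||% seq_along(sample), ns))
  k <- length(sample)
  n <- length(values)
  if (var(values) == 0) {
    res <- list(F = 0, df_between = k - 1L, df_within = n - k, p = 1)
  } else {
    fit <- oneway.test(values ~ grp, var.equal = TRUE)
    res <- list(F = unname(fit$statistic),
                df_between = unname(fit$parameter[1]),
                df_within = unname(fit$parameter[2]),
                p = fit$p.value)
  }
  structure(res, class = "anova_result")
}

#' One-way ANOVA from printed summary statistics
#'
#' Reconstructs the one-way ANOVA F statistic from per-group means, sample
#' standard deviations (denominator `n - 1`) and sizes, as printed in a
#' demographics table: `SSB = sum n_g (m_g - m.)^2` about the weighted
#' grand mean and `SSW = sum (n_g - 1) sd_g^2`.  Algebraically identical to
#' [oneway_anova()] on the raw data the summaries came from.
#'
#' @param stats data frame with columns `group`, `mean`, `sd`, `n`
#'   (`sd >= 0`, `n >= 2`).
#' @return an `anova_result`; `F` is `Inf` when `SSW = 0` with `SSB > 0`.
#' @examples
#' anova_from_summary(data.frame(group = c("ASC", "SIB", "CON"),
#'                               mean = c(104.79, 112.43, 113.43),
#'                               sd = c(14.6, 11.4, 9.1), n = 14))
#' @export
anova_from_summary <- function(stats) {
  need <- c("mean", "sd", "n")
  if (!all(need %in% names(stats)))
    stop("stats must have columns mean, sd, n")
  if (any(stats$sd < 0)) stop("standard deviations must be non-negative")
  if (any(stats$n < 2)) stop("every group needs n >= 2")
  k <- nrow(stats)
  if (k < 2) stop("need at least 2 groups")
  n <- sum(stats$n)
  grand <- sum(stats$n * stats$mean) / n
  ssb <- sum(stats$n * (stats$mean - grand)^2)
  ssw <- sum((stats$n - 1) * stats$sd^2)
  df1 <- k - 1L
  df2 <- n - k
  if (ssw == 0) {
    f <- if (ssb > 0) Inf else 0
  } else {
    f <- (ssb / df1) / (ssw / df2)
  }
  p <- if (is.infinite(f)) 0 else pf(f, df1, df2, lower.tail = FALSE)
  structure(list(F = f, df_between = df1, df_within = df2, p = p),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' Student's pooled two-sample t-test
#'
#' Pooled-variance two-sample t with `df = n1 + n2 - 2` (the planned
#' comparison of this design; two groups of 14 give df = 26), two-sided p.
#'
#' @param a,b numeric vectors with at least 2 values each.
#' @return a `t_test_result`: `t`, `df`, `p`.
#' @export
two_sample_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 values")
  df <- length(a) + length(b) - 2L
  pooled <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) / df
  if (pooled == 0) {
    if (mean(a) == mean(b)) {
      res <- list(t = 0, df = df, p = 1)
    } else {
      res <- list(t = sign(mean(a) - mean(b)) * Inf, df = df, p = 0)
    }
  } else {
    fit <- t.test(a, b, var.equal = TRUE)
    res <- list(t = unname(fit$statistic), df = unname(fit$parameter),
                p = fit$p.value)
  }
  structure(res, class = "t_test_result")
}

#' Cross-condition correlation of a per-subject metric
#'
#' Pairwise Pearson correlations across subjects between conditions, with
#' two-sided p-values from the t transform
#' `t = r sqrt((S - 2) / (1 - r^2))`.
#'
#' @param tab `S x C` matrix or data frame (subjects x conditions), no
#'   missing cells, `S >= 3`, `C >= 2`.
#' @return list with `r` and `p`, both `C x C` matrices.  Entries
#'   involving a constant condition are `NA` (with a warning).
#' @export
condition_correlation <- function(tab) {
  tab <- as.matrix(tab)
  s <- nrow(tab)
  if (s < 3) stop("need at least 3 subjects")
  if (ncol(tab) < 2) stop("need at least 2 conditions")
  if (any(!is.finite(tab))) stop("no missing cells allowed")
  const <- apply(tab, 2, sd) == 0
  if (any(const))
    warning("constant condition column(s): ",
            paste(colnames(tab)[const] %||% which(const), collapse = ", "))
  r <- suppressWarnings(cor(tab))
  r[const, ] <- NA
  r[, const] <- NA
  tstat <- r * sqrt((s - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), s - 2)
  p[abs(r) == 1] <- 0
  diag(p) <- NA
  diag(r) <- 1
  list(r = r, p = p)
}

#' Classify the three-group pattern of a metric
#'
#' Applies the endophenotype decision rule to a CON / SIB / ASC sample:
#' \describe{
#'   \item{endophenotype}{significant ANOVA, group means strictly ordered
#'     `CON > SIB > ASC`, and a significant ASC-vs-CON comparison.  The
#'     SIB-vs-CON comparison is reported but not required: a difference
#'     between affected individuals and their relatives is of interest but
#'     not necessary for an endophenotype.}
#'   \item{reversed_endophenotype}{the same with the ordering inverted
#'     (`CON < SIB < ASC`).}
#'   \item{nonlinear}{significant ANOVA without a monotone ordering.}
#'   \item{none}{otherwise.}
#' }
#'
#' @param sample named list with numeric vectors for exactly `CON`, `SIB`
#'   and `ASC`.
#' @param alpha significance level (default 0.05).
#' @return an `endophenotype_result`: `pattern`, `means`, `anova`,
#'   `t_asc_con`, `t_sib_con`, `alpha`.
#' @export
endophenotype_pattern <- function(sample, alpha = 0.05) {
  need <- c("CON", "SIB", "ASC")
  if (!all(need %in% names(sample)))
    stop("sample must contain groups CON, SIB and ASC")
  sample <- sample[need]
  an <- oneway_anova(sample)
  t_ac <- two_sample_t(sample$ASC, sample$CON)
  t_sc <- two_sample_t(sample$SIB, sample$CON)
  m <- vapply(sample, mean, numeric(1))
  decreasing <- m["CON"] > m["SIB"] && m["SIB"] > m["ASC"]
  increasing <- m["CON"] < m["SIB"] && m["SIB"] < m["ASC"]
  pattern <- if (an$p < alpha && decreasing && t_ac$p < alpha) {
    "endophenotype"
  } else if (an$p < alpha && increasing && t_ac$p < alpha) {
    "reversed_endophenotype"
  } else if (an$p < alpha && !decreasing && !increasing) {
    "nonlinear"
  } else {
    "none"
  }
  structure(list(pattern = pattern, means = m, anova = an,
                 t_asc_con = t_ac, t_sib_con = t_sc, alpha = alpha),
            class = "endophenotype_result")
}

#' @export
print.endophenotype_result <- function(x, ...) {
  cat(sprintf("pattern: %s (means CON %.4g, SIB %.4g, ASC %.4g; ANOVA p = %.3g; ASC-CON p = %.3g)\n",
              x$pattern, x$means["CON"], x$means["SIB"], x$means["ASC"],
              x$anova$p, x$t_asc_con$p))
  invisible(x)
}
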