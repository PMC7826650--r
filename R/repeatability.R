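# One-way random-effects ANOVA mean squares for an n x k matrix (subjects x
# repeated measurements). MSB has n - 1 df, MSW has n(k - 1) df.
.oneway_ms <- function(values) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (anyNA(values)) stop("missing cells are not allowed; analyse complete pairs")
  n <- nrow(values)
  k <- ncol(values)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 measurements")
  row_means <- rowMeans(values)
  grand <- mean(values)
  msb <- k * sum((row_means - grand)^2) / (n - 1)
  msw <- sum((values - row_means)^2) / (n * (k - 1))
  list(msb = msb, msw = msw, n = n, k = k)
}

#' Single-measurement one-way random-effects ICC, ICC(1,1)
#'
#' Point estimate and exact F-based confidence interval for the intraclass
#' correlation under the one-way random-effects model (each subject measured
#' k times, measurements exchangeable within subject):
#' ICC = (MSB - MSW) / (MSB + (k - 1) MSW). The interval comes from the
#' F-ratio MSB/MSW with (n - 1, n(k - 1)) degrees of freedom. Negative
#' estimates are reported as computed - clamping would distort the sampling
#' distribution that the interval coverage relies on.
#'
#' @param values n x k numeric matrix: rows = subjects (lesions), columns =
#'   repeated measurements (visits). No missing cells.
#' @param conf_level confidence level (default 0.95).
#' @return An `icc_result`: list with `icc`, `ci_low`, `ci_high`, `n`, `k`,
#'   `msb`, `msw`, `conf_level`.
#' @export
icc_1_1 <- function(values, conf_level = 0.95) {
  stopifnot(conf_level > 0, conf_level < 1)
  ms <- .oneway_ms(values)
  n <- ms$n; k <- ms$k
  icc <- (ms$msb - ms$msw) / (ms$msb + (k - 1) * ms$msw)
  alpha <- 1 - conf_level
  f_obs <- ms$msb / ms$msw
  fl <- f_obs / qf(1 - alpha / 2, n - 1, n * (k - 1))
  fu <- f_obs * qf(1 - alpha / 2, n * (k - 1), n - 1)
  structure(list(icc = icc,
                 ci_low = (fl - 1) / (fl + k - 1),
                 ci_high = (fu - 1) / (fu + k - 1),
                 n = n, k = k, msb = ms$msb, msw = ms$msw,
                 conf_level = conf_level),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(1,1) = %.3f, %d%% CI [%.3f, %.3f] (n = %d, k = %d)\n",
              x$icc, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$n, x$k))
  invisible(x)
}

#' Multiplier linking the within-subject SD to the repeatability coefficient
#'
#' `sqrt(2) * qnorm((1 + coverage) / 2)`; approximately 2.77 at the default
#' 95% coverage (the familiar 1.96 * sqrt(2)).
#'
#' @param coverage fraction of test-retest differences the RC should bound.
#' @return Scalar multiplier.
#' @export
rc_factor <- function(coverage = 0.95) {
  stopifnot(coverage > 0, coverage < 1)
  sqrt(2) * qnorm((1 + coverage) / 2)
}

#' Repeatability coefficient with confidence interval
#'
#' The repeatability coefficient RC = `rc_factor()` * wSD bounds the absolute
#' difference between two repeat measurements for 95% of subjects, where the
#' within-subject SD is estimated as sqrt(MSW) from the one-way ANOVA (for
#' k = 2 this equals sqrt(sum(d_i^2) / (2n)) over the paired differences).
#' The confidence interval follows from the exact chi-square distribution of
#' n(k - 1) * wSD^2 / sigma_w^2 with n(k - 1) degrees of freedom.
#'
#' RC carries the units of the feature; it is invariant to shifts and scales
#' linearly with the data.
#'
#' @param values n x k numeric matrix as in [icc_1_1()].
#' @param coverage coverage of the RC bound (default 0.95).
#' @param conf_level confidence level of the interval (default 0.95).
#' @return An `rc_result`: list with `rc`, `ci_low`, `ci_high`, `wsd`, `n`,
#'   `k`, `coverage`, `conf_level`.
#' @export
rc <- function(values, coverage = 0.95, conf_level = 0.95) {
  stopifnot(conf_level > 0, conf_level < 1)
  ms <- .oneway_ms(values)
  df <- ms$n * (ms$k - 1)
  wsd <- sqrt(ms$msw)
  fac <- rc_factor(coverage)
  alpha <- 1 - conf_level
  var_low <- df * ms$msw / qchisq(1 - alpha / 2, df)
  var_high <- df * ms$msw / qchisq(alpha / 2, df)
  structure(list(rc = fac * wsd,
                 ci_low = fac * sqrt(var_low),
                 ci_high = fac * sqrt(var_high),
                 wsd = wsd, n = ms$n, k = ms$k,
                 coverage = coverage, conf_level = conf_level),
            class = "rc_result")
}

#' @export
print.rc_result <- function(x, ...) {
  cat(sprintf("RC = %.4g, %d%% CI [%.4g, %.4g] (wSD = %.4g, n = %d, k = %d)\n",
              x$rc, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$wsd, x$n, x$k))
  invisible(x)
}

#' Coefficient of variation of ICCs across datasets
#'
#' SD / mean of ICC point estimates for one feature measured in several
#' datasets (e.g. the same feature across sequences and normalisation
#' settings); a summary of how stable a feature's repeatability is across
#' acquisition choices.
#'
#' @param iccs numeric vector of >= 2 ICC point estimates.
#' @return Scalar CoV; `NA` with a warning when the mean is zero.
#' @export
icc_cov_across_datasets <- function(iccs) {
  stopifnot(is.numeric(iccs), length(iccs) >= 2L)
  m <- mean(iccs)
  if (m == 0) {
    warning("mean ICC is zero; CoV undefined")
    return(NA_real_)
  }
  sd(iccs) / m
}
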