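#' Box-Cox power transformation
#'
#' Forward transform y = (x^lambda - 1) / lambda for lambda != 0 and
#' y = log(x) at lambda = 0, defined for x > 0. Computed via
#' `expm1(lambda * log(x)) / lambda`, which is continuous in lambda through 0
#' to machine precision. Strictly increasing in x for every lambda, so ranks
#' (and hence Spearman correlations) are preserved.
#'
#' @param x positive numeric vector.
#' @param lambda transformation exponent (dimensionless).
#' @return Transformed values.
#' @seealso [boxcox_inverse()], [boxcox_lambda()]
#' @export
boxcox_transform <- function(x, lambda) {
  stopifnot(is.numeric(x), length(lambda) == 1L, is.finite(lambda))
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("Box-Cox transform requires finite positive values")
  }
  if (lambda == 0) log(x) else expm1(lambda * log(x)) / lambda
}

#' Inverse Box-Cox transformation
#'
#' Maps y back to x = (lambda * y + 1)^(1/lambda) (exp(y) at lambda = 0).
#' The inverse only exists where lambda * y + 1 > 0; out-of-domain input is
#' rejected (never clipped) with an error naming the lambda and data range.
#'
#' @param y numeric vector on the transformed scale.
#' @param lambda transformation exponent.
#' @return Values on the original (positive) scale.
#' @export
boxcox_inverse <- function(y, lambda) {
  stopifnot(is.numeric(y), length(lambda) == 1L, is.finite(lambda))
  if (lambda == 0) return(exp(y))
  z <- lambda * y + 1
  if (any(z <= 0)) {
    stop(sprintf(paste0("inverse Box-Cox undefined for lambda = %g over data",
                        " range [%g, %g]: lambda*y + 1 must be positive"),
                 lambda, min(y), max(y)))
  }
  exp(log(z) / lambda)
}

# probability-plot correlation coefficient of Box-Cox transformed data:
# correlation between transformed order statistics and standard normal
# quantiles (the y-axis of a Box-Cox normality plot)
.boxcox_ppcc <- function(x_sorted, q, lambda) {
  y <- boxcox_transform(x_sorted, lambda)
  if (sd(y) == 0) return(-Inf)
  cor(y, q)
}

# profile log-likelihood of the Box-Cox model with Gaussian errors
.boxcox_loglik <- function(x, lambda) {
  y <- boxcox_transform(x, lambda)
  n <- length(x)
  v <- mean((y - mean(y))^2)
  if (v <= 0) return(-Inf)
  -n / 2 * log(v) + (lambda - 1) * sum(log(x))
}

#' Optimal Box-Cox lambda
#'
#' Finds the lambda that makes the transformed sample most Gaussian, by
#' bounded scalar optimisation over `[lower, upper]` (default [-5, 5]) of
#' either the probability-plot correlation coefficient (`"ppcc"`, the
#' criterion displayed on Box-Cox normality plots; the default) or the
#' Gaussian profile log-likelihood (`"mle"`). A coarse grid pass locates the
#' basin before `optimize()` refines it, making the search deterministic and
#' robust to local ripples.
#'
#' @param x positive numeric vector (>= 3 values).
#' @param method `"ppcc"` or `"mle"`.
#' @param lower,upper search bounds for lambda.
#' @param tol optimiser tolerance on lambda.
#' @return The selected lambda (scalar).
#' @export
boxcox_lambda <- function(x, method = c("ppcc", "mle"),
                          lower = -5, upper = 5, tol = 1e-5) {
  method <- match.arg(method)
  stopifnot(length(x) >= 3L, lower < upper)
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("Box-Cox lambda selection requires finite positive values")
  }
  if (sd(x) == 0) stop("cannot select lambda for constant data")
  objective <- if (method == "ppcc") {
    xs <- sort(x)
    q <- qnorm(ppoints(length(x)))
    function(lam) .boxcox_ppcc(xs, q, lam)
  } else {
    function(lam) .boxcox_loglik(x, lam)
  }
  grid <- seq(lower, upper, length.out = 41L)
  vals <- vapply(grid, objective, numeric(1L))
  best <- which.max(vals)
  lo <- grid[max(1L, best - 1L)]
  hi <- grid[min(length(grid), best + 1L)]
  opt <- optimize(objective, lower = lo, upper = hi, maximum = TRUE,
                  tol = tol)
  opt$maximum
}

#' Shapiro-Wilk Gaussianity gate
#'
#' Tests whether pooled feature values are consistent with a Gaussian
#' distribution, failing at the Bonferroni-corrected threshold
#' `alpha / n_features` (default 0.05 / 105). Constant input cannot be tested
#' and fails with a degenerate-distribution flag.
#'
#' @param values numeric vector (3 to 5000 values), typically one feature
#'   pooled across both visits.
#' @param alpha family-wise significance level.
#' @param n_features Bonferroni denominator: the number of features tested.
#' @return List with `p` (Shapiro-Wilk p-value, NA if degenerate), `pass`
#'   (TRUE iff p >= alpha / n_features), `threshold`, and `degenerate`.
#' @export
gaussian_gate <- function(values, alpha = 0.05, n_features = 105L) {
  stopifnot(length(values) >= 3L, alpha > 0, alpha < 1, n_features >= 1L)
  threshold <- alpha / n_features
  if (sd(values) == 0) {
    return(list(p = NA_real_, pass = FALSE, threshold = threshold,
                degenerate = TRUE))
  }
  p <- shapiro.test(values)$p.value
  list(p = p, pass = p >= threshold, threshold = threshold,
       degenerate = FALSE)
}

#' Gaussianity classification and Box-Cox transformation of a feature table
#'
#' Applies the distribution-handling procedure feature by feature: values are
#' pooled across all visits and gated with [gaussian_gate()]. Features that
#' pass are left untransformed (`gaussian_pre`). For the rest, the optimal
#' Box-Cox lambda is fitted on the pooled values (one lambda per feature,
#' applied identically to every visit) and the transformed values are
#' re-gated, yielding `gaussian_post` or `never`. Transformed values replace
#' the originals in the returned table for every feature whose status is not
#' `gaussian_pre` - including `never` features, whose transformed
#' distributions are closer to Gaussian even when still failing the gate.
#'
#' Features with non-positive values (e.g. skewness or cluster shade) are
#' shifted by `-min + eps` before transformation; the shift is recorded per
#' feature.
#'
#' @param ft a [feature_table()].
#' @param alpha,n_features gate parameters, see [gaussian_gate()]. By default
#'   the Bonferroni denominator is the number of features in the table.
#' @param method lambda selection criterion, see [boxcox_lambda()].
#' @return List with `records` (data.frame: feature, sw_p_original, lambda,
#'   sw_p_transformed, status, shift), `table` (the transformed
#'   [feature_table()]), and `counts` (named vector: gaussian_pre,
#'   gaussian_post, never).
#' @export
classify_features <- function(ft, alpha = 0.05, n_features = NULL,
                              method = c("ppcc", "mle")) {
  stopifnot(inherits(ft, "feature_table"))
  method <- match.arg(method)
  feats <- ft_features(ft)
  if (is.null(n_features)) n_features <- length(feats)
  records <- data.frame(feature = feats,
                        sw_p_original = NA_real_,
                        lambda = NA_real_,
                        sw_p_transformed = NA_real_,
                        status = NA_character_,
                        shift = 0,
                        stringsAsFactors = FALSE)
  out <- ft
  for (i in seq_along(feats)) {
    f <- feats[i]
    sel <- out$feature == f
    x <- out$value[sel]
    gate <- gaussian_gate(x, alpha = alpha, n_features = n_features)
    records$sw_p_original[i] <- gate$p
    if (gate$pass) {
      records$status[i] <- "gaussian_pre"
      next
    }
    shift <- 0
    if (min(x) <= 0) {
      span <- max(x) - min(x)
      shift <- -min(x) + (if (span > 0) span else abs(min(x)) + 1) * 1e-6
    }
    xp <- x + shift
    lam <- boxcox_lambda(xp, method = method)
    y <- boxcox_transform(xp, lam)
    gate2 <- gaussian_gate(y, alpha = alpha, n_features = n_features)
    records$lambda[i] <- lam
    records$shift[i] <- shift
    records$sw_p_transformed[i] <- gate2$p
    records$status[i] <- if (gate2$pass) "gaussian_post" else "never"
    out$value[sel] <- y
  }
  counts <- c(gaussian_pre = sum(records$status == "gaussian_pre"),
              gaussian_post = sum(records$status == "gaussian_post"),
              never = sum(records$status == "never"))
  list(records = records, table = feature_table(out), counts = counts)
}
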