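#' Fisher's Z-transformation
#'
#' Variance-stabilising map z = atanh(r) = 0.5 log((1 + r) / (1 - r)) for
#' correlation-type statistics, enabling approximate normal-theory comparison
#' of ICCs. Defined on (-1, 1); |r| = 1 maps to an infinite transform and is
#' rejected.
#'
#' @param r correlation or ICC in (-1, 1).
#' @return z value(s).
#' @export
fisher_z <- function(r) {
  stopifnot(is.numeric(r))
  if (any(abs(r) >= 1)) {
    stop("Fisher's Z-transformation is infinite at |r| = 1; ",
         "values must lie strictly inside (-1, 1)")
  }
  atanh(r)
}

#' Compare two ICCs with Fisher's Z-test
#'
#' Tests whether two ICC(1,1) estimates from independent cohorts differ:
#' both are Z-transformed, the difference z_a - z_b is referenced to a normal
#' distribution with variance summing the per-cohort variances, and
#' significance is judged at the Bonferroni-corrected level
#' `alpha / n_features`. The per-cohort variance uses Fisher's intraclass
#' small-sample form 1/(n - 3/2) for paired (k = 2) designs by default; the
#' classic product-moment form 1/(n - 3) is available via `se`.
#'
#' The cohorts are treated as independent even when they share subjects (an
#' unpaired comparison); with shared subjects the test is conservative in the
#' typical positive-dependence case.
#'
#' @param a,b [icc_1_1()] results, each with n >= 4.
#' @param alpha family-wise significance level.
#' @param n_features Bonferroni denominator (number of features tested).
#' @param conf_level confidence level of the interval on the Z difference.
#' @param se `"intraclass"` (1/(n - 3/2)) or `"classic"` (1/(n - 3)).
#' @return An `icc_comparison`: list with `z_diff`, `se`, `ci_low`,
#'   `ci_high`, `p`, `significant`, `threshold`.
#' @export
compare_iccs <- function(a, b, alpha = 0.05, n_features = 105L,
                         conf_level = 0.95,
                         se = c("intraclass", "classic")) {
  stopifnot(inherits(a, "icc_result"), inherits(b, "icc_result"),
            a$n >= 4L, b$n >= 4L, alpha > 0, alpha < 1)
  se <- match.arg(se)
  offset <- if (se == "intraclass") 1.5 else 3
  z_diff <- fisher_z(a$icc) - fisher_z(b$icc)
  sed <- sqrt(1 / (a$n - offset) + 1 / (b$n - offset))
  p <- 2 * pnorm(-abs(z_diff) / sed)
  zq <- qnorm(1 - (1 - conf_level) / 2)
  threshold <- alpha / n_features
  structure(list(z_diff = z_diff, se = sed,
                 ci_low = z_diff - zq * sed, ci_high = z_diff + zq * sed,
                 p = p, significant = p < threshold, threshold = threshold),
            class = "icc_comparison")
}

#' @export
print.icc_comparison <- function(x, ...) {
  cat(sprintf("Fisher-Z ICC difference: %.3f [%.3f, %.3f], p = %.3g%s\n",
              x$z_diff, x$ci_low, x$ci_high, x$p,
              if (x$significant) " (significant)" else ""))
  invisible(x)
}

#' Volume confounding of radiomic features
#'
#' Absolute Spearman rank correlation of every feature with a reference
#' size feature (mesh volume by default), computed on values pooled across
#' all visits. High |rho| flags features whose apparent repeatability may
#' merely reflect tumour volume. Spearman correlation is rank-based, hence
#' unchanged by Box-Cox transformation of either variable.
#'
#' @param ft a [feature_table()].
#' @param reference name of the reference feature (default
#'   `"shape_mesh_volume"`).
#' @return data.frame with columns `feature` and `abs_spearman_rho` (`NA`
#'   with a warning for constant features).
#' @export
volume_confounding <- function(ft, reference = "shape_mesh_volume") {
  stopifnot(inherits(ft, "feature_table"))
  wide <- ft_widen(ft)
  if (!reference %in% names(wide)) {
    stop("reference feature not present in table: ", reference)
  }
  feats <- setdiff(names(wide), c("lesion_id", "visit", reference))
  rho <- vapply(feats, function(f) {
    x <- wide[[f]]
    if (sd(x, na.rm = TRUE) == 0) {
      warning("feature '", f, "' is constant; Spearman rho undefined")
      return(NA_real_)
    }
    abs(cor(x, wide[[reference]], method = "spearman",
            use = "complete.obs"))
  }, numeric(1L))
  data.frame(feature = feats, abs_spearman_rho = unname(rho),
             stringsAsFactors = FALSE)
}
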