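#' Multi-flip-angle SPGR series
#'
#' Container for a variable-flip-angle spoiled gradient-echo acquisition: one
#' 3D signal volume per flip angle, all sharing a repetition time.
#'
#' @param volumes list of 3D numeric arrays (arbitrary signal units), one per
#'   flip angle; all must share dimensions.
#' @param flip_angles flip angles in degrees, one per volume; at least two
#'   distinct angles are required for T1 fitting.
#' @param tr repetition time (ms), > 0.
#' @param voxel_size optional length-3 voxel edge lengths (mm).
#' @return A `vfa_series` object.
#' @export
vfa_series <- function(volumes, flip_angles, tr, voxel_size = NULL) {
  if (length(flip_angles) == 0L) stop("at least one flip angle is required")
  stopifnot(is.list(volumes), length(volumes) == length(flip_angles), tr > 0)
  if (any(flip_angles <= 0 | flip_angles > 90)) {
    stop("flip angles must lie in (0, 90] degrees")
  }
  dims <- lapply(volumes, dim)
  if (any(vapply(dims, length, integer(1L)) != 3L) ||
      !all(vapply(dims, identical, logical(1L), dims[[1L]]))) {
    stop("all volumes must be 3D arrays of identical dimensions")
  }
  if (length(unique(flip_angles)) < 2L) {
    stop("T1 fitting requires at least 2 distinct flip angles")
  }
  structure(list(volumes = volumes, flip_angles = flip_angles, tr = tr,
                 voxel_size = voxel_size),
            class = "vfa_series")
}

#' Spoiled gradient-echo steady-state signal
#'
#' Forward model S(alpha) = M0 sin(alpha) (1 - E) / (1 - E cos(alpha)) with
#' E = exp(-TR/T1). `m0` and `t1` may be arrays (recycled against each other);
#' `alpha` and `tr` are scalars.
#'
#' @param m0 proton-density scale (arbitrary units).
#' @param t1 longitudinal relaxation time (ms), > 0.
#' @param alpha flip angle (degrees), in (0, 90].
#' @param tr repetition time (ms), > 0.
#' @return Signal in the units of `m0`.
#' @export
spgr_signal <- function(m0, t1, alpha, tr) {
  stopifnot(length(alpha) == 1L, length(tr) == 1L)
  if (any(t1 <= 0)) stop("t1 must be positive")
  if (tr <= 0) stop("tr must be positive")
  if (alpha <= 0 || alpha > 90) stop("alpha must lie in (0, 90] degrees")
  a <- alpha * pi / 180
  e <- exp(-tr / t1)
  m0 * sin(a) * (1 - e) / (1 - e * cos(a))
}

# Linearised DESPOT1 estimate: regressing y = S/sin(a) on x = S/tan(a) gives
# slope E and intercept M0 (1 - E). Vectorised over voxels; returns NA where
# the slope falls outside (0, 1) or the regression is degenerate.
# `signals` is an n_voxel x n_angle matrix.
despot1_fit <- function(signals, flip_angles, tr) {
  a <- flip_angles * pi / 180
  y <- sweep(signals, 2L, sin(a), `/`)
  x <- sweep(signals, 2L, tan(a), `/`)
  nf <- length(a)
  sx <- rowSums(x); sy <- rowSums(y)
  sxx <- rowSums(x * x); sxy <- rowSums(x * y)
  denom <- nf * sxx - sx^2
  slope <- (nf * sxy - sx * sy) / denom
  intercept <- (sy - slope * sx) / nf
  ok <- is.finite(slope) & slope > 0 & slope < 1 & abs(denom) > 0
  t1 <- ifelse(ok, -tr / log(slope), NA_real_)
  m0 <- ifelse(ok, intercept / (1 - slope), NA_real_)
  list(t1 = t1, m0 = m0, ok = ok)
}

# Vectorised Levenberg-Marquardt refinement of (M0, T1) per voxel. All voxels
# iterate simultaneously; the damped 2x2 normal equations are solved in closed
# form. Deterministic: initialisation comes from DESPOT1 (fallback to a fixed
# point), no randomness.
lm_refine_spgr <- function(signals, flip_angles, tr, m0, t1,
                           max_iter = 100L, ftol = 1e-12) {
  a <- flip_angles * pi / 180
  sina <- sin(a); cosa <- cos(a)
  model <- function(m0, t1) {
    e <- exp(-tr / t1)
    num <- outer(1 - e, sina)           # n_voxel x n_angle
    den <- 1 - outer(e, cosa)
    m0 * num / den
  }
  sse <- function(vox, m0, t1) {
    rowSums((signals[vox, , drop = FALSE] - model(m0, t1))^2)
  }
  lambda <- rep(1e-3, length(m0))
  f <- sse(seq_along(m0), m0, t1)
  converged <- rep(FALSE, length(m0))
  for (iter in seq_len(max_iter)) {
    active <- which(!converged)
    if (length(active) == 0L) break
    m0a <- m0[active]; t1a <- t1[active]
    e <- exp(-tr / t1a)
    den <- 1 - outer(e, cosa)
    j1 <- outer(1 - e, sina) / den                     # dS/dM0
    # dS/dT1 = M0 sin(a) (cos(a) - 1) / den^2 * dE/dT1, dE/dT1 = E tr / t1^2
    dedt1 <- e * tr / t1a^2
    j2 <- (m0a * dedt1) * sweep(1 / den^2, 2L, sina * (cosa - 1), `*`)
    r <- signals[active, , drop = FALSE] - m0a * j1    # residuals (S - model)
    a11 <- rowSums(j1 * j1); a12 <- rowSums(j1 * j2); a22 <- rowSums(j2 * j2)
    g1 <- rowSums(j1 * r); g2 <- rowSums(j2 * r)
    improved <- rep(FALSE, length(active))
    for (inner in 1:8) {
      todo <- which(!improved)
      if (length(todo) == 0L) break
      la <- lambda[active][todo]
      m11 <- a11[todo] * (1 + la); m22 <- a22[todo] * (1 + la)
      m12 <- a12[todo]
      det <- m11 * m22 - m12^2
      d1 <- (g1[todo] * m22 - g2[todo] * m12) / det
      d2 <- (g2[todo] * m11 - g1[todo] * m12) / det
      vox <- active[todo]
      m0_new <- m0[vox] + d1
      t1_new <- t1[vox] + d2
      valid <- is.finite(m0_new) & is.finite(t1_new) & t1_new > 0
      f_new <- rep(Inf, length(vox))
      if (any(valid)) {
        f_new[valid] <- sse(vox[valid], m0_new[valid], t1_new[valid])
      }
      acc <- valid & f_new <= f[vox]
      conv_now <- acc & (f[vox] - f_new <= ftol * (f[vox] + ftol))
      if (any(acc)) {
        va <- vox[acc]
        m0[va] <- m0_new[acc]; t1[va] <- t1_new[acc]; f[va] <- f_new[acc]
        lambda[va] <- pmax(lambda[va] / 3, 1e-12)
      }
      lambda[vox[!acc]] <- pmin(lambda[vox[!acc]] * 4, 1e12)
      converged[vox[conv_now]] <- TRUE
      improved[todo[acc]] <- TRUE
    }
    # voxels where no damped step improved the fit are at a (local) optimum
    converged[active[!improved]] <- TRUE
  }
  list(m0 = m0, t1 = t1, sse = f, converged = converged)
}

#' Voxelwise quantitative T1 mapping from a variable-flip-angle series
#'
#' Fits (M0, T1) of the SPGR steady-state equation to each voxel's flip-angle
#' signals by damped nonlinear least squares (Levenberg-Marquardt, vectorised
#' across voxels). Initialisation uses the closed-form linearised DESPOT1
#' solution (regression of S/sin(alpha) on S/tan(alpha)), so the fit is fully
#' deterministic. Voxels whose signals are all (numerically) zero, whose fit
#' fails, or whose T1 lands outside `bounds` are flagged `fit_ok = FALSE` and
#' carry `NA` in the maps; out-of-bounds solutions are flagged, never clamped.
#'
#' No B1 inhomogeneity correction is applied.
#'
#' @param series a [vfa_series()].
#' @param mask optional 3D 0/1 array restricting the fit.
#' @param bounds length-2 positive vector (t1_min, t1_max) in ms.
#' @param method `"lm"` (default): Levenberg-Marquardt refinement of the
#'   DESPOT1 start; `"despot1"`: the linearised closed-form estimate alone,
#'   useful as a fast first pass and as an independent cross-check of the
#'   nonlinear fit.
#' @return A `qt1_map` object: list with 3D arrays `t1` (ms), `m0`, and
#'   logical `fit_ok`.
#' @export
fit_t1_map <- function(series, mask = NULL, bounds = c(1, 10000),
                       method = c("lm", "despot1")) {
  method <- match.arg(method)
  stopifnot(inherits(series, "vfa_series"),
            length(bounds) == 2L, all(bounds > 0), bounds[1L] < bounds[2L])
  dims <- dim(series$volumes[[1L]])
  nvox_total <- prod(dims)
  idx <- if (is.null(mask)) {
    seq_len(nvox_total)
  } else {
    stopifnot(identical(dim(mask), dims))
    which(mask != 0)
  }
  signals <- vapply(series$volumes, function(v) v[idx],
                    numeric(length(idx)))
  if (length(idx) == 1L) signals <- matrix(signals, nrow = 1L)

  t1_out <- array(NA_real_, dim = dims)
  m0_out <- array(NA_real_, dim = dims)
  ok_out <- array(FALSE, dim = dims)

  peak <- max(abs(signals))
  degenerate <- rowSums(abs(signals) > max(peak, 1) * 1e-12) == 0L
  fit_idx <- which(!degenerate)
  if (length(fit_idx) > 0L) {
    s <- signals[fit_idx, , drop = FALSE]
    init <- despot1_fit(s, series$flip_angles, series$tr)
    if (method == "despot1") {
      fit <- list(t1 = init$t1, m0 = init$m0, converged = init$ok)
    } else {
      m0_0 <- ifelse(init$ok, init$m0, apply(abs(s), 1L, max) * 2)
      t1_0 <- ifelse(init$ok, pmin(pmax(init$t1, bounds[1L]), bounds[2L]), 800)
      fit <- lm_refine_spgr(s, series$flip_angles, series$tr, m0_0, t1_0)
    }
    ok <- fit$converged & is.finite(fit$t1) & is.finite(fit$m0) &
      fit$t1 > bounds[1L] & fit$t1 < bounds[2L]
    vox <- idx[fit_idx]
    t1_out[vox[ok]] <- fit$t1[ok]
    m0_out[vox[ok]] <- fit$m0[ok]
    ok_out[vox[ok]] <- TRUE
  }
  structure(list(t1 = t1_out, m0 = m0_out, fit_ok = ok_out,
                 flip_angles = series$flip_angles, tr = series$tr,
                 bounds = bounds),
            class = "qt1_map")
}

#' @export
print.qt1_map <- function(x, ...) {
  n_ok <- sum(x$fit_ok)
  cat(sprintf("qT1 map: %s voxels, %d fitted", paste(dim(x$t1), collapse = "x"),
              n_ok))
  if (n_ok > 0L) {
    cat(sprintf(", T1 median %.0f ms (range %.0f-%.0f)",
                median(x$t1[x$fit_ok]), min(x$t1[x$fit_ok]),
                max(x$t1[x$fit_ok])))
  }
  cat("\n")
  invisible(x)
}
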