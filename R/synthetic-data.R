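#' Specify a one-way random-effects generator for test-retest data
#'
#' Defines the generative truth for a synthetic two-visit feature: lesion i,
#' visit j takes the value g(mu + b_i + e_ij) with b_i ~ N(0, sigma_b^2)
#' (between-lesion) and e_ij ~ N(0, sigma_w^2) (within-lesion, i.e.
#' test-retest error). g is the identity, or an inverse Box-Cox map when
#' `lambda_skew` is given, so that the forward Box-Cox transform with the same
#' lambda restores Gaussianity exactly. Under this model the true ICC(1,1) is
#' sigma_b^2 / (sigma_b^2 + sigma_w^2) and the true repeatability coefficient
#' is `rc_factor()` * sigma_w on the Gaussian scale.
#'
#' Lesions are treated as independent sampling units; patient-level clustering
#' of lesions is deliberately not modelled (a documented limitation shared
#' with per-lesion clinical analyses).
#'
#' @param mu feature mean (feature units).
#' @param sigma_b between-lesion SD, >= 0.
#' @param sigma_w within-lesion SD, > 0.
#' @param n_lesions number of lesions, >= 2.
#' @param n_visits measurements per lesion; default 2, the paired test-retest
#'   design. Larger k is supported for checking the general one-way ANOVA
#'   forms.
#' @param lambda_skew optional Box-Cox lambda used to induce non-Gaussian skew
#'   via the inverse transform; `NULL` for Gaussian output.
#' @param seed optional integer seed applied before this feature's draws.
#' @param feature feature name used in generated tables.
#' @return A `random_effects_spec` object.
#' @seealso [simulate_feature_table()], [true_icc()]
#' @export
random_effects_spec <- function(mu, sigma_b, sigma_w, n_lesions,
                                n_visits = 2L, lambda_skew = NULL,
                                seed = NULL, feature = "feature") {
  stopifnot(is.numeric(mu), length(mu) == 1L,
            is.numeric(sigma_b), length(sigma_b) == 1L, sigma_b >= 0,
            is.numeric(sigma_w), length(sigma_w) == 1L, sigma_w > 0,
            n_lesions >= 2L, n_visits >= 2L)
  if (!is.null(lambda_skew)) {
    stopifnot(is.numeric(lambda_skew), length(lambda_skew) == 1L,
              is.finite(lambda_skew))
  }
  structure(list(mu = mu, sigma_b = sigma_b, sigma_w = sigma_w,
                 n_lesions = as.integer(n_lesions),
                 n_visits = as.integer(n_visits),
                 lambda_skew = lambda_skew,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 feature = feature),
            class = "random_effects_spec")
}

#' True variance-component ICC of a generator spec
#' @param spec a [random_effects_spec()].
#' @return sigma_b^2 / (sigma_b^2 + sigma_w^2), in [0, 1).
#' @export
true_icc <- function(spec) {
  stopifnot(inherits(spec, "random_effects_spec"))
  spec$sigma_b^2 / (spec$sigma_b^2 + spec$sigma_w^2)
}

#' Simulate a two-visit feature table with known variance components
#'
#' Draws each feature from its one-way random-effects model (see
#' [random_effects_spec()]). When a spec carries `lambda_skew`, values are
#' mapped through the inverse Box-Cox transform with that lambda; the map must
#' be invertible over the generated range, otherwise an error names the
#' offending lambda and range (values are never clipped, so the generative
#' truth stays exact).
#'
#' @param specs a single [random_effects_spec()] or a list of them (one per
#'   feature; features are drawn sequentially from one RNG stream).
#' @param seed top-level integer seed; a spec's own `seed` takes precedence
#'   for that feature.
#' @return A [feature_table()].
#' @export
simulate_feature_table <- function(specs, seed = 1L) {
  if (inherits(specs, "random_effects_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1L,
            all(vapply(specs, inherits, logical(1L), "random_effects_spec")))
  set.seed(as.integer(seed))
  parts <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    if (!is.null(sp$seed)) set.seed(sp$seed)
    b <- rnorm(sp$n_lesions, 0, sp$sigma_b)
    e <- matrix(rnorm(sp$n_lesions * sp$n_visits, 0, sp$sigma_w),
                sp$n_lesions, sp$n_visits)
    y <- sp$mu + b + e
    x <- if (is.null(sp$lambda_skew)) y else boxcox_inverse(y, sp$lambda_skew)
    parts[[i]] <- data.frame(
      lesion_id = rep(sprintf("L%04d", seq_len(sp$n_lesions)), sp$n_visits),
      visit = rep(seq_len(sp$n_visits), each = sp$n_lesions),
      feature = sp$feature,
      value = as.vector(x),
      stringsAsFactors = FALSE)
  }
  feature_table(do.call(rbind, parts))
}

#' Specify a multi-flip-angle SPGR phantom
#'
#' Describes a digital phantom: a uniform background with an ellipsoidal
#' "lesion", each with a known T1, imaged with a spoiled gradient-echo
#' sequence at several flip angles. Defaults mirror a 1.5 T liver protocol:
#' flip angles 2, 10, 20 degrees at TR = 4 ms; background T1 500 ms (liver
#' parenchyma) and lesion T1 1000 ms (metastases have prolonged T1).
#'
#' @param grid_shape integer vector of 3 voxel counts.
#' @param voxel_size numeric vector of 3 voxel edge lengths (mm).
#' @param flip_angles flip angles in degrees, each in (0, 90]; >= 1 required
#'   (>= 2 distinct for T1 fitting).
#' @param tr repetition time (ms), > 0.
#' @param t1_background,t1_lesion T1 values (ms), > 0.
#' @param m0 proton-density scale (arbitrary units).
#' @param noise_sd SD of additive Gaussian noise (signal units), >= 0.
#' @param lesion_geometry list with `centre` and `semiaxes` (both length-3,
#'   voxel units); the ellipsoid must fit inside the grid.
#' @param seed integer seed for the noise draws.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(32L, 32L, 32L),
                         voxel_size = c(3, 3, 3),
                         flip_angles = c(2, 10, 20),
                         tr = 4,
                         t1_background = 500, t1_lesion = 1000,
                         m0 = 1000, noise_sd = 0,
                         lesion_geometry = list(centre = grid_shape / 2 + 0.5,
                                                semiaxes = c(5, 5, 3)),
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L),
            length(voxel_size) == 3L, all(voxel_size > 0),
            tr > 0, t1_background > 0, t1_lesion > 0, noise_sd >= 0,
            is.list(lesion_geometry),
            length(lesion_geometry$centre) == 3L,
            length(lesion_geometry$semiaxes) == 3L,
            all(lesion_geometry$semiaxes > 0))
  if (length(flip_angles) == 0L) stop("at least one flip angle is required")
  if (any(flip_angles <= 0 | flip_angles > 90)) {
    stop("flip angles must lie in (0, 90] degrees")
  }
  ctr <- lesion_geometry$centre
  ax <- lesion_geometry$semiaxes
  if (any(ctr - ax < 0.5) || any(ctr + ax > grid_shape + 0.5)) {
    stop("lesion ellipsoid does not fit inside the grid")
  }
  structure(list(grid_shape = grid_shape, voxel_size = voxel_size,
                 flip_angles = flip_angles, tr = tr,
                 t1_background = t1_background, t1_lesion = t1_lesion,
                 m0 = m0, noise_sd = noise_sd,
                 lesion_geometry = lesion_geometry,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Rasterise an ellipsoid into a binary voxel mask
#'
#' A voxel (integer coordinates i, j, k, centre at (i, j, k)) is inside when
#' sum(((c - centre) / semiaxes)^2) <= 1.
#'
#' @param grid_shape integer vector of 3 voxel counts.
#' @param centre,semiaxes length-3 numeric vectors in voxel units.
#' @return A 3D 0/1 integer array.
#' @export
ellipsoid_mask <- function(grid_shape, centre, semiaxes) {
  stopifnot(length(grid_shape) == 3L, length(centre) == 3L,
            length(semiaxes) == 3L, all(semiaxes > 0))
  dx <- (seq_len(grid_shape[1L]) - centre[1L]) / semiaxes[1L]
  dy <- (seq_len(grid_shape[2L]) - centre[2L]) / semiaxes[2L]
  dz <- (seq_len(grid_shape[3L]) - centre[3L]) / semiaxes[3L]
  q <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
  array(as.integer(q <= 1), dim = grid_shape)
}

#' Simulate a multi-flip-angle SPGR phantom series
#'
#' Generates one volume per flip angle with voxel values
#' `spgr_signal(m0, t1_voxel, alpha, tr)` plus additive Gaussian noise, along
#' with the ground-truth T1 and M0 maps and the lesion mask.
#'
#' @param spec a [phantom_spec()].
#' @return A list with components `series` (a [vfa_series()]), `t1` and `m0`
#'   (truth arrays), `mask` (0/1 array), and `spec`.
#' @export
simulate_vfa_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  mask <- ellipsoid_mask(spec$grid_shape, spec$lesion_geometry$centre,
                         spec$lesion_geometry$semiaxes)
  t1 <- array(spec$t1_background, dim = spec$grid_shape)
  t1[mask == 1L] <- spec$t1_lesion
  m0 <- array(spec$m0, dim = spec$grid_shape)
  volumes <- lapply(spec$flip_angles, function(a) {
    s <- spgr_signal(m0, t1, a, spec$tr)
    if (spec$noise_sd > 0) {
      s <- s + array(rnorm(length(s), 0, spec$noise_sd), dim = dim(s))
    }
    s
  })
  list(series = vfa_series(volumes, spec$flip_angles, spec$tr,
                           voxel_size = spec$voxel_size),
       t1 = t1, m0 = m0, mask = mask, spec = spec)
}
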