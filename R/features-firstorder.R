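#' First-order intensity features of an ROI
#'
#' Standard histogram-free intensity statistics of the ROI voxel values:
#' location, spread, skewness (Fisher-Pearson moment coefficient, population
#' moments), energy (sum of squared intensities), total energy (energy scaled
#' by the physical voxel volume), and root-mean-square. Skewness requires at
#' least 3 voxels and non-zero variance; otherwise it is returned as `NA`.
#'
#' @param values numeric vector of ROI voxel intensities (>= 1 value).
#' @param voxel_volume physical volume of one voxel (mm^3); needed for
#'   `firstorder_total_energy` (NA if omitted).
#' @return Named numeric vector with prefix `firstorder_`.
#' @export
first_order_features <- function(values, voxel_volume = NULL) {
  values <- as.numeric(values)
  if (length(values) < 1L || anyNA(values)) {
    stop("values must be a non-empty numeric vector without NAs")
  }
  n <- length(values)
  m <- mean(values)
  energy <- sum(values^2)
  m2 <- mean((values - m)^2)  # population variance
  skew <- if (n >= 3L && m2 > 0) mean((values - m)^3) / m2^1.5 else NA_real_
  c(firstorder_mean = m,
    firstorder_median = median(values),
    firstorder_minimum = min(values),
    firstorder_maximum = max(values),
    firstorder_range = max(values) - min(values),
    firstorder_variance = m2,
    firstorder_skewness = skew,
    firstorder_energy = energy,
    firstorder_total_energy = if (is.null(voxel_volume)) NA_real_ else
      energy * voxel_volume,
    firstorder_rms = sqrt(energy / n))
}
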