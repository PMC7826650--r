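#' Image plus region-of-interest container
#'
#' Bundles a 3D intensity array, a binary lesion mask of the same shape, and
#' the voxel size. Intensities may be arbitrary signal units (weighted
#' images) or ms (quantitative T1 maps).
#'
#' @param image 3D numeric array.
#' @param mask 3D 0/1 array, same shape, with at least one voxel set.
#' @param voxel_size length-3 positive voxel edge lengths (mm).
#' @return A `roi_image` object.
#' @export
roi_image <- function(image, mask, voxel_size = c(1, 1, 1)) {
  stopifnot(length(dim(image)) == 3L, identical(dim(mask), dim(image)),
            length(voxel_size) == 3L, all(voxel_size > 0))
  if (sum(mask != 0) < 1L) stop("mask must contain at least one voxel")
  structure(list(image = image, mask = (mask != 0) * 1L,
                 voxel_size = as.numeric(voxel_size)),
            class = "roi_image")
}

#' Linear intensity normalisation
#'
#' Rescales intensities to a target mean and SD (defaults 0 and 100, the
#' standard linear normalisation convention for MR radiomics). By default the
#' statistics are computed over the whole volume; set `scope = "roi"` to use
#' ROI voxels only. The mask is unchanged.
#'
#' @param img a [roi_image()].
#' @param target_mean,target_sd target moments; `target_sd` > 0.
#' @param scope `"volume"` (default) or `"roi"`: where the mean/SD are
#'   measured.
#' @return A [roi_image()] with normalised intensities.
#' @export
normalise_image <- function(img, target_mean = 0, target_sd = 100,
                            scope = c("volume", "roi")) {
  stopifnot(inherits(img, "roi_image"), target_sd > 0)
  scope <- match.arg(scope)
  vals <- if (scope == "roi") img$image[img$mask == 1L] else as.vector(img$image)
  s <- sd(vals)
  if (!is.finite(s) || s == 0) {
    stop("cannot normalise a constant image (SD is zero)")
  }
  out <- (img$image - mean(vals)) / s * target_sd + target_mean
  roi_image(out, img$mask, img$voxel_size)
}

#' Fixed-bin-width grey-level discretisation
#'
#' Assigns each ROI voxel an integer grey level
#' `floor((x - min_roi) / bin_width) + 1`, anchoring bin edges at the ROI
#' minimum. The number of bins is the maximum grey level; voxels outside the
#' mask are ignored (NA in the output).
#'
#' @param img a [roi_image()].
#' @param bin_width bin width in intensity units, > 0 (default 5).
#' @return A list with `levels` (integer 3D array, NA outside the mask),
#'   `n_bins`, and `bin_width`.
#' @export
discretise <- function(img, bin_width = 5) {
  stopifnot(inherits(img, "roi_image"), bin_width > 0)
  inside <- img$mask == 1L
  if (!any(inside)) stop("mask is empty")
  x <- img$image[inside]
  lev <- as.integer(floor((x - min(x)) / bin_width)) + 1L
  levels <- array(NA_integer_, dim = dim(img$image))
  levels[inside] <- lev
  list(levels = levels, n_bins = max(lev), bin_width = bin_width)
}

#' Nearest-neighbour mask resampling between voxel grids
#'
#' Resamples a binary mask from one voxel grid to another (e.g. up-sampling a
#' low-resolution qT1-map mask onto a higher-resolution weighted image).
#' Grids are assumed axis-aligned with a shared corner at the world origin;
#' each target voxel takes the value of the source voxel containing its
#' centre. Nearest-neighbour interpolation guarantees a binary result.
#'
#' @param mask 3D 0/1 array.
#' @param source_voxel_size,target_voxel_size length-3 positive voxel sizes
#'   (mm).
#' @param target_shape length-3 positive integer output dimensions.
#' @return A 3D 0/1 integer array of dimension `target_shape`.
#' @export
resample_mask <- function(mask, source_voxel_size, target_voxel_size,
                          target_shape) {
  stopifnot(length(dim(mask)) == 3L,
            length(source_voxel_size) == 3L, all(source_voxel_size > 0),
            length(target_voxel_size) == 3L, all(target_voxel_size > 0))
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3L || any(target_shape < 1L)) {
    stop("target shape must be 3 positive integers")
  }
  src_shape <- dim(mask)
  axis_index <- function(ax) {
    centres <- (seq_len(target_shape[ax]) - 0.5) * target_voxel_size[ax]
    j <- floor(centres / source_voxel_size[ax]) + 1L
    j[j < 1L | j > src_shape[ax]] <- NA_integer_
    j
  }
  ix <- axis_index(1L); iy <- axis_index(2L); iz <- axis_index(3L)
  out <- array(0L, dim = target_shape)
  okx <- !is.na(ix); oky <- !is.na(iy); okz <- !is.na(iz)
  if (any(okx) && any(oky) && any(okz)) {
    out[okx, oky, okz] <- (mask[ix[okx], iy[oky], iz[okz], drop = FALSE] != 0) * 1L
  }
  out
}
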