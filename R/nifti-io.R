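#' Read and write volumes as NIfTI
#'
#' Thin wrappers around RNifti keeping the package's array + voxel-size
#' convention: a plain 3D array plus a length-3 voxel size (mm) recorded in
#' the NIfTI header.
#'
#' @param x 3D numeric array.
#' @param path file path (`.nii` or `.nii.gz`).
#' @param voxel_size length-3 voxel edge lengths (mm).
#' @return `write_volume` returns the path invisibly; `read_volume` returns a
#'   list with `data` (3D array) and `voxel_size`.
#' @export
write_volume <- function(x, path, voxel_size = c(1, 1, 1)) {
  stopifnot(length(dim(x)) == 3L, length(voxel_size) == 3L,
            all(voxel_size > 0))
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim = dim(img)),
       voxel_size = RNifti::pixdim(img)[1:3])
}

#' Read an image/mask pair into an ROI container
#'
#' @param image_path,mask_path NIfTI file paths; geometries must agree.
#' @return A [roi_image()].
#' @export
read_roi_nifti <- function(image_path, mask_path) {
  img <- read_volume(image_path)
  msk <- read_volume(mask_path)
  if (!identical(dim(img$data), dim(msk$data))) {
    stop("image and mask dimensions differ")
  }
  roi_image(img$data, msk$data != 0, img$voxel_size)
}
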