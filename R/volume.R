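#' 3D activity-concentration volume
#'
#' A reconstructed, attenuation/scatter-corrected SPECT volume in absolute
#' units. Voxel values are activity concentrations in Bq/mL on a regular grid.
#'
#' @param grid 3D numeric array, Bq/mL, all values >= 0.
#' @param spacing_mm Voxel spacing per axis, mm (length 3, > 0).
#' @param origin_mm Physical position of the first voxel's center, mm
#'   (length 3).
#' @return Object of class `activity_volume`.
#' @export
activity_volume <- function(grid, spacing_mm = c(1, 1, 1),
                            origin_mm = c(0, 0, 0)) {
  if (length(dim(grid)) != 3L) stop("grid must be a 3D array")
  if (any(grid < 0)) stop("activity concentrations must be >= 0")
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  if (any(spacing_mm <= 0)) stop("voxel spacing must be strictly positive")
  structure(list(grid = grid, spacing_mm = spacing_mm,
                 origin_mm = rep_len(as.numeric(origin_mm), 3L)),
            class = "activity_volume")
}

#' @export
print.activity_volume <- function(x, ...) {
  cat(sprintf("<activity_volume %s voxels @ %s mm, max %.3g Bq/mL>\n",
              paste(dim(x$grid), collapse = "x"),
              paste(format(x$spacing_mm), collapse = "x"), max(x$grid)))
  invisible(x)
}

#' @export
print.suv_volume <- function(x, ...) {
  cat(sprintf("<suv_volume %s voxels @ %s mm, max %.3f g/mL, patient %s>\n",
              paste(dim(x$grid), collapse = "x"),
              paste(format(x$spacing_mm), collapse = "x"), max(x$grid),
              x$patient_id %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write volumes as NIfTI-1
#'
#' Volumes are stored as float32 NIfTI-1 (`.nii` / `.nii.gz`); spacing is
#' taken from `pixdim` and the origin from the quaternion/affine translation.
#'
#' @param path NIfTI file path.
#' @return `read_activity_volume` returns an [activity_volume()].
#' @export
read_activity_volume <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected a 3D NIfTI volume: ", path)
  grid <- array(as.numeric(img), dim(img))  # plain array, no header attrs
  spacing <- RNifti::pixdim(img)[1:3]
  org <- RNifti::xform(img)[1:3, 4]  # world position of voxel (0,0,0)
  activity_volume(grid, spacing_mm = spacing, origin_mm = org)
}

#' @rdname read_activity_volume
#' @param vol An `activity_volume` or `suv_volume`.
#' @export
write_volume_nifti <- function(vol, path) {
  arr <- vol$grid
  attr(arr, "pixdim") <- vol$spacing_mm
  attr(arr, "pixunits") <- c("mm", "s")
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "float"), path)
  invisible(path)
}
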