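#' Read a 3D volume from a NIfTI-1 file
#'
#' Reads a scalar 3D image, taking the voxel spacing from the file header
#' (`pixdim`).  Values are cast to double.
#'
#' @param path path to a `.nii` or `.nii.gz` file holding a 3D image.
#' @param units unit flag to attach, `"SUV"` (default) or `"Bq/mL"`.
#' @return An [suv_volume].
#' @seealso [read_mask()] for binary masks, [write_volume()].
#' @export
read_volume <- function(path, units = c("SUV", "Bq/mL")) {
  units <- match.arg(units)
  if (!file.exists(path)) stopf("no such file: %s", path)
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (is.null(dm)) dm <- length(img)
  while (length(dm) > 3L && dm[length(dm)] == 1L) dm <- dm[-length(dm)]
  if (length(dm) > 3L)
    stopf("%s: expected a 3D image, got %d dimensions", path, length(dm))
  # trailing singleton dimensions are dropped by the reader; restore them
  if (length(dm) < 3L) dm <- c(dm, rep(1L, 3L - length(dm)))
  sp <- RNifti::pixdim(img)
  sp <- c(sp, rep(1, 3))[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stopf("%s: non-positive voxel spacing in header", path)
  a <- array(as.numeric(img), dm)
  suv_volume(a, spacing = sp, units = units)
}

#' Read a binary mask from a NIfTI-1 file
#'
#' @param path path to a NIfTI file whose nonzero voxels define the mask.
#' @return A [binary_mask].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  binary_mask(v$values != 0, grid = v$grid)
}

#' Write a volume or mask to a NIfTI-1 file
#'
#' Volumes are stored as 64-bit floats (lossless round trip); masks as
#' 8-bit unsigned integers.  The header spacing is set from the object's
#' grid.
#'
#' @param vol an [suv_volume] or [binary_mask].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  is_mask <- inherits(vol, "binary_mask")
  if (!is_mask && !inherits(vol, "suv_volume"))
    stopf("write_volume expects an suv_volume or binary_mask")
  if (any(!is.finite(vol$values)))
    stopf("refusing to write non-finite voxel values to %s", path)
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$grid$spacing
  ok <- try(RNifti::writeNifti(img, path,
                               datatype = if (is_mask) "uint8" else "double"),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stopf("failed to write NIfTI file %s: %s", path, as.character(ok))
  invisible(path)
}

#' Convert an activity image to standardized uptake values
#'
#' Body-weight SUV: `SUV(x) = activity(x) * body_weight / injected_dose`,
#' with activity in Bq/mL, dose in Bq and weight in grams (1 g ~ 1 mL of
#' tissue).  The input is assumed decay-corrected; no decay model is
#' applied.
#'
#' @param activity an [suv_volume] holding activity concentration (Bq/mL).
#' @param injected_dose injected dose in Bq (> 0).
#' @param body_weight patient body weight in grams (> 0).
#' @return A dimensionless [suv_volume] flagged `"SUV"`.
#' @examples
#' a <- suv_volume(array(5000, c(2, 2, 2)), units = "Bq/mL")
#' s <- to_suv(a, injected_dose = 2e8, body_weight = 7e4)
#' s$values[1]  # 1.75
#' @export
to_suv <- function(activity, injected_dose, body_weight) {
  if (!inherits(activity, "suv_volume"))
    stopf("to_suv expects an suv_volume")
  if (!is.finite(injected_dose) || injected_dose <= 0)
    stopf("injected_dose must be a positive number of Bq")
  if (!is.finite(body_weight) || body_weight <= 0)
    stopf("body_weight must be a positive number of grams")
  suv_volume(activity$values * (body_weight / injected_dose),
             grid = activity$grid, units = "SUV")
}
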