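#' Voxel grid geometry
#'
#' A `grid3d` couples the voxel counts of a 3D image with its physical
#' spacing in millimetres per voxel.  Voxel indices are 0-based in world
#' terms: voxel `(i, j, k)` (0-based) sits at world position
#' `(i * sx, j * sy, k * sz)` mm.  PET grids are typically anisotropic, with
#' the slice spacing larger than the in-plane spacing (e.g. 2.73 x 2.73 x
#' 3.27 mm on a Discovery 690 scanner).
#'
#' @param shape integer vector of length 3, voxel counts per axis (all >= 1).
#' @param spacing numeric vector of length 3, mm per voxel (all > 0).
#' @return An object of class `grid3d` with elements `shape` and `spacing`.
#' @examples
#' g <- grid3d(c(64, 64, 48), c(2.73, 2.73, 3.27))
#' g$spacing
#' @export
grid3d <- function(shape, spacing = c(2.73, 2.73, 3.27)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stopf("grid shape must be 3 positive integers")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("grid spacing must be 3 positive reals (mm)")
  structure(list(shape = shape, spacing = spacing), class = "grid3d")
}

#' @export
print.grid3d <- function(x, ...) {
  cat(sprintf("<grid3d> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) && all(abs(a$spacing - b$spacing) < tol)
}

#' SUV / activity volume
#'
#' A 3D scalar PET image together with its grid.  Values are either raw
#' activity concentration (Bq/mL) or dimensionless standardized uptake
#' values (SUV); the `units` flag records which.
#'
#' @param values 3D numeric array of finite values.
#' @param spacing voxel spacing in mm (length 3), or a [grid3d] via `grid`.
#' @param units `"SUV"` or `"Bq/mL"`.
#' @param grid optional [grid3d]; overrides `spacing`.
#' @return An object of class `suv_volume` with elements `values`, `grid`,
#'   `units`.
#' @export
suv_volume <- function(values, spacing = c(2.73, 2.73, 3.27),
                       units = c("SUV", "Bq/mL"), grid = NULL) {
  units <- match.arg(units)
  if (!is.array(values) || length(dim(values)) != 3L)
    stopf("volume values must be a 3D array")
  if (any(!is.finite(values)))
    stopf("volume contains non-finite values (NaN/Inf not allowed)")
  storage.mode(values) <- "double"
  g <- if (is.null(grid)) grid3d(dim(values), spacing) else grid
  if (!identical(g$shape, as.integer(dim(values))))
    stopf("grid shape does not match array dimensions")
  structure(list(values = values, grid = g, units = units),
            class = "suv_volume")
}

#' @export
print.suv_volume <- function(x, ...) {
  cat(sprintf("<suv_volume> [%s] range %.4g..%.4g\n", x$units,
              min(x$values), max(x$values)))
  print(x$grid)
  invisible(x)
}

#' Binary mask volume
#'
#' A 3D mask on the same grid conventions as [suv_volume]; voxels take
#' values in `{0, 1}` with 1 = inside (lesion / ROI / prediction).
#'
#' @param values 3D array coercible to 0/1 (logical or numeric).
#' @param spacing voxel spacing in mm, or `grid`.
#' @param grid optional [grid3d].
#' @return An object of class `binary_mask` with elements `values`
#'   (0/1 double array) and `grid`.
#' @export
binary_mask <- function(values, spacing = c(2.73, 2.73, 3.27), grid = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stopf("mask values must be a 3D array")
  v <- values
  if (is.logical(v)) v <- v + 0
  if (any(!v %in% c(0, 1)))
    stopf("mask values must all be 0 or 1")
  storage.mode(v) <- "double"
  g <- if (is.null(grid)) grid3d(dim(v), spacing) else grid
  if (!identical(g$shape, as.integer(dim(v))))
    stopf("grid shape does not match array dimensions")
  structure(list(values = v, grid = g), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d / %d voxels inside\n",
              sum(x$values), length(x$values)))
  print(x$grid)
  invisible(x)
}

# Accept a classed volume/mask or a bare array; return the 3D array.
vol_array <- function(x) {
  if (inherits(x, "suv_volume") || inherits(x, "binary_mask")) return(x$values)
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  stopf("expected an suv_volume, binary_mask, or 3D array")
}

vol_grid <- function(x, default_spacing = c(1, 1, 1)) {
  if (inherits(x, "suv_volume") || inherits(x, "binary_mask")) return(x$grid)
  grid3d(dim(vol_array(x)), default_spacing)
}
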