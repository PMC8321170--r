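#' @name presegmentation
#' @title From a rough ROI to an ellipsoidal surface initialization
#' @description
#' The active surface is started from an ellipsoid built out of a rough
#' user region of interest: the hottest voxel inside the ROI anchors a
#' threshold-connected seed region, whose second moments define the
#' ellipsoid's center, principal axes and semi-axes.  The only hard
#' requirement on the initialization is that it envelops part of the
#' tumor and contains the maximum-intensity voxel.
NULL

#' Hottest voxel within an ROI
#'
#' Ties are broken by the lowest flattened (x-fastest) index.
#'
#' @param vol an [suv_volume] or 3D array.
#' @param roi a non-empty [binary_mask] or 0/1 array on the same grid.
#' @return Integer vector `(i, j, k)` (1-based array index).
#' @export
find_max_voxel <- function(vol, roi) {
  v <- vol_array(vol)
  r <- vol_array(roi)
  if (!identical(dim(v), dim(r))) stopf("volume and roi must share a grid")
  if (!any(r != 0)) stopf("roi is empty")
  masked <- ifelse(r != 0, v, -Inf)
  as.integer(arrayInd(which.max(masked), dim(v)))
}

#' Threshold-connected seed region inside the ROI
#'
#' The 26-connected component, containing the maximum voxel, of
#' `{x in roi : vol(x) >= frac * max}`.  The component is non-empty by
#' construction (the maximum voxel always qualifies).  `seed_region` is
#' monotone in `frac`: a larger fraction yields a subset.
#'
#' @inheritParams find_max_voxel
#' @param frac threshold as a fraction of the ROI maximum, in (0, 1];
#'   default 0.4 (the common 40%-of-max PET practice).
#' @return A [binary_mask] of the seed region.
#' @export
seed_region <- function(vol, roi, frac = 0.4) {
  if (!(frac > 0 && frac <= 1)) stopf("frac must lie in (0, 1]")
  v <- vol_array(vol)
  r <- vol_array(roi)
  mx <- find_max_voxel(v, r)
  vmax <- v[mx[1], mx[2], mx[3]]
  cand <- (r != 0) & (v >= frac * vmax)
  lab <- label_components(cand, connectivity = 26)
  comp <- lab[mx[1], mx[2], mx[3]]
  g <- if (inherits(roi, "binary_mask")) roi$grid
       else if (inherits(vol, "suv_volume")) vol$grid
       else grid3d(dim(v), c(1, 1, 1))
  binary_mask(lab == comp, grid = g)
}

#' Ellipsoid object
#'
#' @param center voxel-space center (length 3, 0-based continuous index).
#' @param semi_axes semi-axis lengths in voxels (all > 0).
#' @param orientation 3x3 rotation matrix whose columns are the principal
#'   axes.
#' @return An object of class `ellipsoid`.
#' @export
ellipsoid <- function(center, semi_axes, orientation = diag(3)) {
  if (any(semi_axes <= 0)) stopf("semi-axes must be positive")
  R <- orientation
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    stopf("orientation must be orthonormal")
  if (det(R) < 0) R[, 3] <- -R[, 3]  # enforce det +1
  structure(list(center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes), orientation = R),
            class = "ellipsoid")
}

# Normalized ellipsoid coordinate: q <= 1 inside.
ellipsoid_q <- function(e, pts) {
  # pts: n x 3 matrix of 0-based voxel coordinates
  local <- (pts - matrix(e$center, nrow(pts), 3, byrow = TRUE)) %*% e$orientation
  sqrt((local[, 1] / e$semi_axes[1])^2 + (local[, 2] / e$semi_axes[2])^2 +
         (local[, 3] / e$semi_axes[3])^2)
}

#' Fit an enveloping ellipsoid to a seed region
#'
#' Center = voxel centroid of the seed (intensity-free); axes = principal
#' axes of the seed's second-moment tensor; semi-axes =
#' `scale * sqrt(eigenvalues)`, floored at 2 voxels.  For a solid
#' ellipsoidal seed the moment eigenvalues are `a^2/5`, so `scale =
#' sqrt(5) ~ 2.24` reproduces the seed extent; the default 2.6 envelops
#' it with a modest margin.  Degenerate seeds (< 4 voxels or coplanar)
#' fall back to a sphere of radius 3 voxels at the centroid.  If
#' `max_voxel` is given, semi-axes are grown uniformly until the
#' ellipsoid contains it.
#'
#' Moments are computed in voxel units so the ellipsoid lives on the
#' index grid like the level-set field it initializes.
#'
#' @param seed a non-empty [binary_mask].
#' @param scale semi-axis multiplier on the moment square roots.
#' @param max_voxel optional 1-based `(i, j, k)` index that the ellipsoid
#'   must contain.
#' @return An [ellipsoid] (voxel coordinates, 0-based center).
#' @export
fit_ellipsoid <- function(seed, scale = 2.6, max_voxel = NULL) {
  m <- vol_array(seed)
  idx <- which(m != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stopf("seed mask is empty")
  pts <- idx - 1 # 0-based voxel coordinates
  ctr <- colMeans(pts)
  fallback <- nrow(idx) < 4L
  if (!fallback) {
    M <- stats::cov(pts) * (nrow(pts) - 1) / nrow(pts) # population moments
    eig <- eigen(M, symmetric = TRUE)
    if (min(eig$values) < 1e-8) fallback <- TRUE # coplanar/collinear
  }
  e <- if (fallback) {
    ellipsoid(ctr, c(3, 3, 3))
  } else {
    ellipsoid(ctr, pmax(scale * sqrt(eig$values), 2), eig$vectors)
  }
  if (!is.null(max_voxel)) {
    q <- ellipsoid_q(e, matrix(as.numeric(max_voxel) - 1, 1, 3))
    if (q > 1) e$semi_axes <- e$semi_axes * q * 1.05
  }
  e
}

#' @export
print.ellipsoid <- function(x, ...) {
  cat(sprintf("<ellipsoid> center (%.2f, %.2f, %.2f) vox, semi-axes (%.2f, %.2f, %.2f) vox\n",
              x$center[1], x$center[2], x$center[3],
              x$semi_axes[1], x$semi_axes[2], x$semi_axes[3]))
  invisible(x)
}

#' Signed-distance initialization from an ellipsoid
#'
#' Evaluates an approximate signed distance to the ellipsoid surface
#' (`(q - 1) * min(semi_axes)`, negative inside) on the voxel grid and
#' re-distances it numerically with [reinitialize()].
#'
#' @param e an [ellipsoid] in voxel coordinates.
#' @param grid a [grid3d] (or integer shape vector).
#' @return A 3D numeric array: the level-set field, negative inside.
#' @export
ellipsoid_to_levelset <- function(e, grid) {
  d <- if (inherits(grid, "grid3d")) grid$shape else as.integer(grid)
  ctr1 <- e$center + 1 # 1-based
  if (any(ctr1 < 1) || any(ctr1 > d))
    stopf("ellipsoid center lies outside the grid")
  pts <- as.matrix(expand.grid(i = seq_len(d[1]) - 1, j = seq_len(d[2]) - 1,
                               k = seq_len(d[3]) - 1))
  q <- ellipsoid_q(e, pts)
  phi <- array((q - 1) * min(e$semi_axes), d)
  reinitialize(phi)
}
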