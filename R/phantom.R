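#' Specification of a synthetic PET phantom
#'
#' Describes a PET-like volume with a known tumor support: a bright tumor
#' region over a dim background, smoothed by an isotropic Gaussian
#' point-spread function (PSF) specified in world mm, plus additive noise.
#' Geometry is defined in world coordinates so shapes are physically
#' meaningful on anisotropic grids.  The gold-standard mask is the exact
#' noiseless geometric support (a voxel belongs to a shape iff its center
#' is inside the implicit surface); partial-volume softening enters only
#' through the PSF applied to the intensity image.
#'
#' Default levels emulate a high-contrast FDG-avid lesion: tumor uptake 8
#' SUV over background 1 SUV (8:1 contrast), additive Gaussian noise with
#' sd 0.4 SUV (5% of the tumor level) and a 5 mm FWHM PSF, on a
#' 64 x 64 x 48 grid with 2.73 x 2.73 x 3.27 mm voxels.
#'
#' @param shape_kind one of `"sphere"`, `"ellipsoid"`, `"bilobed"`,
#'   `"torus"`, `"two_blobs"`.
#' @param grid_shape voxel counts per axis.
#' @param spacing mm per voxel.
#' @param tumor_uptake,background_uptake SUV-like plateau levels; tumor
#'   must exceed background.
#' @param noise_sigma additive Gaussian noise sd (SUV units, >= 0).
#' @param psf_fwhm_mm isotropic Gaussian blur FWHM in world mm (>= 0).
#' @param noise_model `"gaussian"` (default) or `"poisson"` (values drawn
#'   as `rpois(v * poisson_scale) / poisson_scale`).
#' @param poisson_scale counts per SUV unit for the Poisson model.
#' @param seed integer RNG seed; identical specs and seeds give
#'   bit-identical phantoms.
#' @param geom named list overriding shape geometry (all in mm):
#'   `radius` (sphere); `semi_axes` (ellipsoid); `radii`, `separation`
#'   (bilobed / two_blobs); `ring_radius`, `tube_radius` (torus);
#'   `center` (all shapes; defaults to the grid center).
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(shape_kind = c("sphere", "ellipsoid", "bilobed",
                                        "torus", "two_blobs"),
                         grid_shape = c(64, 64, 48),
                         spacing = c(2.73, 2.73, 3.27),
                         tumor_uptake = 8, background_uptake = 1,
                         noise_sigma = 0.4, psf_fwhm_mm = 5,
                         noise_model = c("gaussian", "poisson"),
                         poisson_scale = 25, seed = 1, geom = list()) {
  shape_kind <- match.arg(shape_kind)
  noise_model <- match.arg(noise_model)
  g <- grid3d(grid_shape, spacing)
  if (!(tumor_uptake > background_uptake))
    stopf("tumor_uptake must exceed background_uptake")
  if (noise_sigma < 0 || psf_fwhm_mm < 0)
    stopf("noise_sigma and psf_fwhm_mm must be >= 0")
  structure(list(shape_kind = shape_kind, grid = g,
                 tumor_uptake = tumor_uptake,
                 background_uptake = background_uptake,
                 noise_sigma = noise_sigma, psf_fwhm_mm = psf_fwhm_mm,
                 noise_model = noise_model, poisson_scale = poisson_scale,
                 seed = as.integer(seed), geom = geom),
            class = "phantom_spec")
}

# World-coordinate arrays of voxel centers (0-based index * spacing).
world_coords <- function(grid) {
  d <- grid$shape; sp <- grid$spacing
  xs <- (seq_len(d[1]) - 1) * sp[1]
  ys <- (seq_len(d[2]) - 1) * sp[2]
  zs <- (seq_len(d[3]) - 1) * sp[3]
  list(x = array(rep(xs, times = d[2] * d[3]), d),
       y = array(rep(rep(ys, each = d[1]), times = d[3]), d),
       z = array(rep(zs, each = d[1] * d[2]), d))
}

phantom_geometry <- function(spec) {
  g <- spec$grid
  ctr <- (g$shape - 1) / 2 * g$spacing
  geom <- spec$geom
  ctr <- if (!is.null(geom$center)) geom$center else ctr
  switch(spec$shape_kind,
    sphere = list(center = ctr,
                  radius = geom$radius %||% 24),
    ellipsoid = list(center = ctr,
                     semi_axes = geom$semi_axes %||% c(28, 22, 18)),
    bilobed = list(center = ctr,
                   radii = geom$radii %||% c(20, 16),
                   separation = geom$separation %||% 26),
    torus = list(center = ctr,
                 ring_radius = geom$ring_radius %||% 24,
                 tube_radius = geom$tube_radius %||% 9),
    two_blobs = list(center = ctr,
                     radii = geom$radii %||% c(14, 12),
                     separation = geom$separation %||% 60))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

phantom_inside <- function(spec, w) {
  geo <- phantom_geometry(spec)
  c0 <- geo$center
  dx <- w$x - c0[1]; dy <- w$y - c0[2]; dz <- w$z - c0[3]
  switch(spec$shape_kind,
    sphere = dx^2 + dy^2 + dz^2 <= geo$radius^2,
    ellipsoid = (dx / geo$semi_axes[1])^2 + (dy / geo$semi_axes[2])^2 +
      (dz / geo$semi_axes[3])^2 <= 1,
    bilobed = {
      h <- geo$separation / 2
      ((dx + h)^2 + dy^2 + dz^2 <= geo$radii[1]^2) |
        ((dx - h)^2 + dy^2 + dz^2 <= geo$radii[2]^2)
    },
    torus = (sqrt(dx^2 + dy^2) - geo$ring_radius)^2 + dz^2 <=
      geo$tube_radius^2,
    two_blobs = {
      h <- geo$separation / 2
      ((dx + h)^2 + dy^2 + dz^2 <= geo$radii[1]^2) |
        ((dx - h)^2 + dy^2 + dz^2 <= geo$radii[2]^2)
    })
}

gaussian_kernel_3d <- function(sigma_vox) {
  k1 <- lapply(sigma_vox, function(s) {
    if (s <= 0) return(1)
    r <- max(1L, as.integer(ceiling(4 * s)))
    k <- exp(-0.5 * (seq.int(-r, r) / s)^2)
    k / sum(k)
  })
  k <- outer(outer(k1[[1]], k1[[2]]), k1[[3]])
  array(k, c(length(k1[[1]]), length(k1[[2]]), length(k1[[3]])))
}

#' Generate a synthetic PET phantom
#'
#' Builds the gold-standard mask from the implicit shape (voxel-center
#' test), forms `background + (tumor - background) * mask`, applies the
#' PSF as a normalized Gaussian convolution (per-axis sigma converted from
#' world mm by the voxel spacing), adds noise, and clips at zero.
#'
#' @param spec a [phantom_spec].
#' @return A list with elements `volume` (an [suv_volume]) and `gold`
#'   (a [binary_mask] holding the exact shape support).
#' @examples
#' ph <- generate_phantom(phantom_spec(grid_shape = c(24, 24, 16),
#'                                     geom = list(radius = 10),
#'                                     noise_sigma = 0, psf_fwhm_mm = 0))
#' sum(ph$gold$values)
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid
  w <- world_coords(g)
  inside <- phantom_inside(spec, w)
  if (!any(inside)) stopf("phantom shape is empty on this grid")
  # the shape must fit strictly inside the grid
  d <- g$shape
  edge <- inside
  edge[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- FALSE
  if (any(edge)) stopf("phantom shape does not fit within the grid")
  img <- spec$background_uptake +
    (spec$tumor_uptake - spec$background_uptake) * (inside + 0)
  if (spec$psf_fwhm_mm > 0) {
    sigma_vox <- (spec$psf_fwhm_mm / (2 * sqrt(2 * log(2)))) / g$spacing
    kern <- gaussian_kernel_3d(sigma_vox)
    plan <- conv_plan(d, kern)
    num <- conv_exec(plan, img)$a
    den <- conv_exec(plan, array(1, d))$a  # edge renormalization
    img <- num / den
  }
  if (spec$noise_sigma > 0 || spec$noise_model == "poisson") {
    img <- with_seed(spec$seed, {
      if (spec$noise_model == "gaussian") {
        img + stats::rnorm(length(img), 0, spec$noise_sigma)
      } else {
        stats::rpois(length(img), pmax(img, 0) * spec$poisson_scale) /
          spec$poisson_scale
      }
    })
    dim(img) <- d
  }
  img <- pmax(img, 0)
  dim(img) <- d
  list(volume = suv_volume(img, grid = g, units = "SUV"),
       gold = binary_mask(inside, grid = g))
}

#' Axis-aligned ROI box around a mask
#'
#' Emulates the rough user region of interest that encircles the lesion:
#' the bounding box of the mask, dilated by `margin_voxels` per axis and
#' clipped to the grid.
#'
#' @param mask a non-empty [binary_mask].
#' @param margin_voxels non-negative integer dilation per axis.
#' @return A [binary_mask] covering the dilated bounding box.
#' @export
roi_around <- function(mask, margin_voxels = 4L) {
  stopifnot(inherits(mask, "binary_mask"))
  m <- as.integer(margin_voxels)
  if (m < 0) stopf("margin_voxels must be >= 0")
  idx <- which(mask$values != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stopf("roi_around: mask is empty")
  d <- mask$grid$shape
  lo <- pmax(apply(idx, 2, min) - m, 1L)
  hi <- pmin(apply(idx, 2, max) + m, d)
  out <- array(0, d)
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1
  binary_mask(out, grid = mask$grid)
}
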