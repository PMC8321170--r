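#' @name tissue_sampling
#' @title 3x3x3 window sampling and tissue labelling
#' @description
#' Training data for the tissue classifier are 27-element intensity
#' vectors: each 3x3x3 voxel window is flattened in a fixed axis order
#' (x fastest, then y, then z) and labelled from the gold-standard mask
#' by the number of lesion voxels it contains: 0 -> background, 1-17 ->
#' border-line, 18-27 -> lesion.
NULL

tissue_levels <- c("lesion", "border_line", "background")

# 3x3x3 window offsets, x-fastest flattening (documented model order).
window_offsets <- function() {
  as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
}

#' Tissue label from a window's lesion-voxel count
#'
#' A 27-voxel window totally outside the gold standard is background; one
#' with no more than 17 lesion voxels (but at least one) is border-line;
#' all other windows (18-27 lesion voxels) are lesion.
#'
#' @param lesion_count integer vector with values in 0..27.
#' @return Factor with levels `lesion`, `border_line`, `background`.
#' @examples
#' label_from_window(c(0, 17, 18, 27))
#' @export
label_from_window <- function(lesion_count) {
  n <- as.integer(lesion_count)
  if (any(is.na(n)) || any(n < 0L) || any(n > 27L))
    stopf("lesion_count must be integers in 0..27")
  lab <- ifelse(n == 0L, "background",
                ifelse(n <= 17L, "border_line", "lesion"))
  factor(lab, levels = tissue_levels)
}

#' Extract labelled 27-vector samples from a volume
#'
#' One sample per interior voxel (windows that would leave the grid are
#' skipped during training extraction), so a volume of shape
#' `(nx, ny, nz)` yields `(nx-2) * (ny-2) * (nz-2)` samples.  Labels
#' depend only on the gold mask, never on the intensities.
#'
#' @param vol an [suv_volume] (or 3D array).
#' @param gold a [binary_mask] on the same grid.
#' @return An object of class `pet_samples`: list with `X` (n x 27 matrix,
#'   columns in x-fastest window order), `label` (factor), `center`
#'   (n x 3 integer matrix of 1-based window-center indices).
#' @export
extract_samples <- function(vol, gold) {
  v <- vol_array(vol)
  m <- vol_array(gold)
  if (!identical(dim(v), dim(m)))
    stopf("volume and gold mask must share a grid")
  if (inherits(vol, "suv_volume") && inherits(gold, "binary_mask") &&
      !same_grid(vol$grid, gold$grid))
    stopf("volume and gold mask must share a grid")
  d <- dim(v)
  if (any(d < 3L)) stopf("grid must be at least 3 voxels in every axis")
  core <- list(2:(d[1] - 1L), 2:(d[2] - 1L), 2:(d[3] - 1L))
  off <- window_offsets()
  n <- prod(d - 2L)
  X <- matrix(0, n, 27L)
  cnt <- integer(n)
  for (r in seq_len(nrow(off))) {
    sl <- lapply(1:3, function(ax) core[[ax]] + off[r, ax])
    X[, r] <- as.vector(v[sl[[1]], sl[[2]], sl[[3]]])
    cnt <- cnt + as.integer(m[sl[[1]], sl[[2]], sl[[3]]] != 0)
  }
  centers <- as.matrix(expand.grid(i = core[[1]], j = core[[2]], k = core[[3]]))
  structure(list(X = X, label = label_from_window(cnt),
                 center = centers),
            class = "pet_samples")
}

#' @export
print.pet_samples <- function(x, ...) {
  cc <- class_counts(x)
  cat(sprintf("<pet_samples> %d samples (%d lesion, %d border-line, %d background)\n",
              nrow(x$X), cc[1], cc[2], cc[3]))
  invisible(x)
}

#' Per-class sample counts
#'
#' @param samples a `pet_samples` object (or a factor of labels).
#' @return Named integer vector `(n_lesion, n_border, n_background)`.
#' @export
class_counts <- function(samples) {
  lab <- if (inherits(samples, "pet_samples")) samples$label else samples
  lab <- factor(lab, levels = tissue_levels)
  tab <- table(lab)
  c(n_lesion = as.integer(tab[["lesion"]]),
    n_border = as.integer(tab[["border_line"]]),
    n_background = as.integer(tab[["background"]]))
}

# Subset helper used by the classifier's splits.
samples_subset <- function(samples, idx) {
  structure(list(X = samples$X[idx, , drop = FALSE],
                 label = samples$label[idx],
                 center = samples$center[idx, , drop = FALSE]),
            class = "pet_samples")
}
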