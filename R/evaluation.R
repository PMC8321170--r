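#' Voxelwise confusion counts of two masks
#'
#' @param pred,gold [binary_mask]s (or 0/1 arrays) on the same grid; the
#'   second argument is the reference.
#' @return Named integer vector `(TP, FP, FN, TN)` summing to the voxel
#'   count.
#' @export
confusion_counts <- function(pred, gold) {
  p <- vol_array(pred) != 0
  g <- vol_array(gold) != 0
  if (!identical(dim(p), dim(g))) stopf("masks must share a grid")
  c(TP = sum(p & g), FP = sum(p & !g), FN = sum(!p & g), TN = sum(!p & !g))
}

#' Rate metrics from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, positive
#' predictive value `TP/(TP+FP)`, accuracy
#' `(TP+TN)/(TP+FP+FN+TN)` and Dice similarity coefficient
#' `2TP/(2TP+FP+FN)`.  An empty denominator (e.g. sensitivity of an
#' empty reference) is defined as 1 and flagged in the `degenerate`
#' attribute so degenerate sweeps do not crash.
#'
#' @param counts a named vector as returned by [confusion_counts()], or a
#'   `pred` mask (in which case `gold` must be given).
#' @param gold optional reference mask.
#' @return Named numeric vector `(sensitivity, specificity, ppv,
#'   accuracy, dsc)` with attribute `counts` and, when a 0/0 convention
#'   was used, `degenerate`.
#' @examples
#' seg_rates(c(TP = 2, FP = 1, FN = 1, TN = 96))
#' @export
seg_rates <- function(counts, gold = NULL) {
  if (!is.null(gold)) counts <- confusion_counts(counts, gold)
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  fn <- counts[["FN"]]; tn <- counts[["TN"]]
  degenerate <- character(0)
  rate <- function(num, den, name) {
    if (den == 0) {
      degenerate <<- c(degenerate, name)
      return(1)
    }
    num / den
  }
  out <- c(sensitivity = rate(tp, tp + fn, "sensitivity"),
           specificity = rate(tn, tn + fp, "specificity"),
           ppv = rate(tp, tp + fp, "ppv"),
           accuracy = rate(tp + tn, tp + fp + fn + tn, "accuracy"),
           dsc = rate(2 * tp, 2 * tp + fp + fn, "dsc"))
  attr(out, "counts") <- counts
  if (length(degenerate)) attr(out, "degenerate") <- degenerate
  out
}

# Surface voxels: mask voxels with at least one face-adjacent background
# (grid-exterior counts as background).
surface_voxels <- function(m) {
  inside <- m != 0
  nb <- array(TRUE, dim(m))
  for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))) {
    nb <- nb & (shift_arr(inside + 0, s, pad = "zero") != 0)
  }
  which(inside & !nb, arr.ind = TRUE)
}

directed_hausdorff <- function(A, B) {
  # max over rows of A of the min Euclidean distance to rows of B
  worst <- 0
  step <- 512L
  B2 <- rowSums(B^2)
  for (start in seq(1L, nrow(A), by = step)) {
    rows <- start:min(start + step - 1L, nrow(A))
    Ai <- A[rows, , drop = FALSE]
    d2 <- outer(rowSums(Ai^2), B2, "+") - 2 * tcrossprod(Ai, B)
    worst <- max(worst, max(apply(d2, 1, min)))
  }
  sqrt(pmax(worst, 0))
}

#' Hausdorff distance between two masks
#'
#' `HD = max{d(A, B), d(B, A)}` where `d(A, B)` is the maximum over
#' boundary voxels of `A` of the Euclidean distance to the nearest
#' boundary voxel of `B`.  Boundary voxels are mask voxels with a
#' face-adjacent background voxel.  In `"mm"` mode coordinates are scaled
#' per axis by the voxel spacing.
#'
#' @param a,b non-empty [binary_mask]s (or 0/1 arrays) on the same grid.
#' @param units `"voxel"` (default) or `"mm"`.
#' @param spacing spacing override when bare arrays are passed.
#' @return Non-negative scalar distance.
#' @export
hausdorff_distance <- function(a, b, units = c("voxel", "mm"),
                               spacing = NULL) {
  units <- match.arg(units)
  ma <- vol_array(a); mb <- vol_array(b)
  if (!identical(dim(ma), dim(mb))) stopf("masks must share a grid")
  if (!any(ma != 0) || !any(mb != 0)) stopf("hausdorff needs non-empty masks")
  A <- surface_voxels(ma)
  B <- surface_voxels(mb)
  if (units == "mm") {
    sp <- if (!is.null(spacing)) spacing
          else if (inherits(a, "binary_mask")) a$grid$spacing
          else stopf("mm units need a binary_mask or an explicit spacing")
    A <- sweep(A, 2, sp, "*")
    B <- sweep(B, 2, sp, "*")
  }
  max(directed_hausdorff(A, B), directed_hausdorff(B, A))
}

#' Pearson correlation coefficient
#'
#' Sample covariance over the product of sample standard deviations
#' (delegates to [stats::cor()]); +1/-1 indicate total (anti)correlation
#' between two paired score lists, 0 none.
#'
#' @param x,y numeric vectors of equal length >= 2, each with non-zero
#'   variance.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_cc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stopf("pearson_cc needs two equal-length vectors of length >= 2")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("pearson_cc is undefined for zero-variance input")
  stats::cor(x, y)
}

#' Full evaluation report for a predicted mask
#'
#' @param pred,gold [binary_mask]s on the same grid.
#' @param hd_units `"voxel"` (default) or `"mm"`.
#' @return List with `counts`, `rates` (see [seg_rates()]), `hd`, and
#'   `hd_units`.
#' @export
evaluate_masks <- function(pred, gold, hd_units = c("voxel", "mm")) {
  hd_units <- match.arg(hd_units)
  counts <- confusion_counts(pred, gold)
  rates <- seg_rates(counts)
  hd <- if (any(vol_array(pred) != 0) && any(vol_array(gold) != 0))
    hausdorff_distance(pred, gold, units = hd_units) else NA_real_
  list(counts = as.list(counts),
       rates = as.list(unclass(rates)[seq_along(rates)]),
       hd = hd, hd_units = hd_units)
}
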