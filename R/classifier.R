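#' @name da_classifier
#' @title Regularized linear discriminant tissue classifier
#' @description
#' Three-class linear discriminant analysis (LDA) over 27-element window
#' vectors.  A single pooled within-class covariance `Sigma` is estimated
#' and ridge-regularized (`Sigma + gamma * I`); the discriminant score of
#' class `c` for a vector `v` is
#' `delta_c(v) = v' Sigma^-1 mu_c - mu_c' Sigma^-1 mu_c / 2 + log pi_c`
#' and the predicted class is the argmax.  Regularization is essential
#' here because near-constant background windows make the 27x27 pooled
#' covariance rank-deficient on high-contrast, low-noise data.
NULL

fit_lda_core <- function(X, y, gamma = NULL) {
  y <- factor(y)
  cls <- levels(droplevels(y))
  if (length(cls) < 2L) stopf("need at least 2 classes present to train")
  X <- as.matrix(X)
  p <- ncol(X)
  n <- nrow(X)
  if (n < length(cls)) stopf("need at least one sample per class")
  means <- t(vapply(cls, function(cc) colMeans(X[y == cc, , drop = FALSE]),
                    numeric(p)))
  Sw <- matrix(0, p, p)
  for (cc in cls) {
    Xc <- X[y == cc, , drop = FALSE]
    Xc <- sweep(Xc, 2, means[cc, ])
    Sw <- Sw + crossprod(Xc)
  }
  # with fewer samples than dimensions the pooled covariance is rank
  # deficient; the ridge gamma must then carry the inversion
  Sw <- Sw / max(n - length(cls), 1L)
  if (is.null(gamma)) gamma <- 1e-6 * mean(diag(Sw))
  Sg <- Sw + diag(gamma, p)
  ch <- try(chol(Sg), silent = TRUE)
  if (inherits(ch, "try-error"))
    stopf("pooled covariance is singular; raise the regularization gamma")
  W <- chol2inv(ch) %*% t(means)            # p x C
  priors <- as.numeric(table(y)[cls]) / n
  b <- -0.5 * colSums(t(means) * W) + log(priors)
  structure(list(classes = cls, means = means, cov = Sw, gamma = gamma,
                 priors = priors, W = W, b = b, p = p),
            class = "da_model")
}

#' Discriminant scores and predicted classes
#'
#' @param model a `da_model` from [da_train()].
#' @param X matrix of row vectors (same dimension the model was trained on).
#' @return List with `scores` (n x C matrix of discriminant scores),
#'   `class` (factor of argmax predictions) and `lesion_margin`
#'   (lesion-vs-rest score margin, `NA` if the model has no lesion class).
#' @export
da_predict <- function(model, X) {
  stopifnot(inherits(model, "da_model"))
  X <- as.matrix(X)
  if (ncol(X) != model$p)
    stopf("expected %d feature columns, got %d", model$p, ncol(X))
  S <- X %*% model$W
  S <- sweep(S, 2, model$b, "+")
  colnames(S) <- model$classes
  pred <- factor(model$classes[max.col(S, ties.method = "first")],
                 levels = model$classes)
  margin <- if ("lesion" %in% model$classes && length(model$classes) > 1L) {
    rest <- S[, setdiff(model$classes, "lesion"), drop = FALSE]
    S[, "lesion"] - apply(rest, 1, max)
  } else NA_real_
  list(scores = S, class = pred, lesion_margin = margin)
}

binary_rates <- function(truth_pos, pred_pos) {
  tp <- sum(truth_pos & pred_pos); fn <- sum(truth_pos & !pred_pos)
  tn <- sum(!truth_pos & !pred_pos); fp <- sum(!truth_pos & pred_pos)
  c(sensitivity = if (tp + fn > 0) tp / (tp + fn) else 1,
    specificity = if (tn + fp > 0) tn / (tn + fp) else 1)
}

eval_on <- function(model, X, y, positive = "lesion") {
  pr <- da_predict(model, X)
  y <- factor(as.character(y), levels = model$classes)
  acc <- mean(as.character(pr$class) == as.character(y))
  if (!positive %in% model$classes) positive <- model$classes[1]
  pos <- as.character(y) == positive
  score <- if (identical(positive, "lesion") && !all(is.na(pr$lesion_margin)))
    pr$lesion_margin
  else pr$scores[, positive] - apply(pr$scores[, setdiff(model$classes, positive),
                                              drop = FALSE], 1, max)
  auc <- if (any(pos) && any(!pos)) roc_auc(score, pos) else NA_real_
  rt <- binary_rates(pos, as.character(pr$class) == positive)
  c(accuracy = acc, rt, auc = auc)
}

#' Train the tissue classifier with a stratified 80/20 split
#'
#' The samples are split per class into a seeded random 80% training /
#' 20% testing partition; the model is fitted on the training part and
#' held-out metrics (accuracy, lesion-vs-rest sensitivity/specificity and
#' ROC AUC) are attached.
#'
#' @param samples a `pet_samples` object (see [extract_samples()]), or any
#'   list with `X` (matrix) and `label` (factor).
#' @param gamma ridge regularization strength; default
#'   `1e-6 * trace(Sigma) / p`.
#' @param seed integer seed for the split.
#' @param test_fraction held-out fraction (default 0.2).
#' @return A `da_model` with element `heldout` (named metric vector) and
#'   `heldout_n`.
#' @export
da_train <- function(samples, gamma = NULL, seed = 1, test_fraction = 0.2) {
  X <- samples$X
  y <- factor(samples$label)
  n <- nrow(X)
  idx_test <- with_seed(seed, {
    unlist(lapply(levels(droplevels(y)), function(cc) {
      ids <- which(y == cc)
      ntest <- floor(test_fraction * length(ids))
      if (ntest > 0) sample(ids, ntest) else integer(0)
    }))
  })
  idx_train <- setdiff(seq_len(n), idx_test)
  model <- fit_lda_core(X[idx_train, , drop = FALSE], y[idx_train], gamma)
  if (length(idx_test) > 0) {
    model$heldout <- eval_on(model, X[idx_test, , drop = FALSE], y[idx_test])
    model$heldout_n <- length(idx_test)
  }
  model
}

#' @export
print.da_model <- function(x, ...) {
  cat(sprintf("<da_model> classes: %s; gamma = %.3g\n",
              paste(x$classes, collapse = ", "), x$gamma))
  if (!is.null(x$heldout)) {
    cat(sprintf("  held-out (n=%d): %s\n", x$heldout_n,
                paste(sprintf("%s=%.4f", names(x$heldout), x$heldout),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Stratified k-fold cross-validation of the classifier
#'
#' Each class's samples are distributed evenly over `k` folds; each fold
#' serves once as validation while the model is trained on the rest.
#'
#' @inheritParams da_train
#' @param k number of folds (default 5; up to the sample count, which is
#'   leave-one-out).  Every class needs at least 2 members so all
#'   training folds contain all classes.
#' @return List with `folds` (per-fold data.frame of accuracy,
#'   sensitivity, specificity, auc), `mean` and `sd` (named vectors), and
#'   `k`.
#' @export
da_kfold_cv <- function(samples, k = 5, gamma = NULL, seed = 1) {
  X <- samples$X
  y <- factor(samples$label)
  k <- as.integer(k)
  if (k < 2L) stopf("k must be at least 2")
  cls <- levels(droplevels(y))
  if (k > nrow(X))
    stopf("k = %d exceeds the number of samples (%d)", k, nrow(X))
  smallest <- min(table(droplevels(y)))
  if (smallest < 2L)
    stopf("every class needs at least 2 members for stratified folds (smallest class has %d)",
          smallest)
  fold <- integer(nrow(X))
  with_seed(seed, {
    pos <- 0L
    for (cc in cls) {
      ids <- sample(which(y == cc))
      # continue the fold cycle across classes so no fold stays empty
      fold[ids] <- ((pos + seq_along(ids) - 1L) %% k) + 1L
      pos <- pos + length(ids)
    }
  })
  res <- lapply(seq_len(k), function(f) {
    tr <- fold != f
    model <- fit_lda_core(X[tr, , drop = FALSE], y[tr], gamma)
    eval_on(model, X[!tr, , drop = FALSE], y[!tr])
  })
  folds <- as.data.frame(do.call(rbind, res))
  folds <- cbind(fold = seq_len(k), folds)
  list(folds = folds,
       mean = colMeans(folds[, -1, drop = FALSE]),
       sd = apply(folds[, -1, drop = FALSE], 2, stats::sd),
       k = k)
}

#' Area under the ROC curve
#'
#' Probability that a random positive sample scores above a random
#' negative one; ties count one half (equivalent to the trapezoidal rule
#' on the empirical ROC).  Computed from mid-ranks.
#'
#' @param scores numeric scores (larger = more positive).
#' @param labels logical or 0/1 vector, `TRUE`/1 = positive.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  pos <- as.logical(labels)
  if (length(pos) != length(scores)) stopf("scores and labels differ in length")
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stopf("both classes must be present for AUC")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Three-class characteristic maps
#'
#' Aligned binary indicator fields for the lesion, border-line and
#' background tissue classes; at every voxel exactly one of the three
#' equals 1.
#'
#' @param chi_lesion,chi_border,chi_background 3D 0/1 arrays of equal
#'   dimension.
#' @param grid a [grid3d].
#' @return An object of class `class_maps`.
#' @export
class_maps <- function(chi_lesion, chi_border, chi_background, grid) {
  stopifnot(identical(dim(chi_lesion), dim(chi_border)),
            identical(dim(chi_lesion), dim(chi_background)))
  tot <- chi_lesion + chi_border + chi_background
  if (any(tot != 1))
    stopf("class maps must partition the grid (exactly one 1 per voxel)")
  structure(list(chi_lesion = chi_lesion + 0, chi_border = chi_border + 0,
                 chi_background = chi_background + 0, grid = grid),
            class = "class_maps")
}

#' @export
print.class_maps <- function(x, ...) {
  cat(sprintf("<class_maps> lesion %d, border-line %d, background %d voxels\n",
              sum(x$chi_lesion), sum(x$chi_border), sum(x$chi_background)))
  invisible(x)
}

#' Classify every voxel of a volume
#'
#' Applies the trained window classifier at every voxel: the volume is
#' edge-replicated so boundary voxels also get a full 3x3x3 window, and
#' each voxel is assigned the argmax discriminant class of its window
#' vector.  Because the discriminants are linear, the per-class score
#' field is a 27-tap linear filter of the volume, which is how it is
#' computed.
#'
#' @param model a `da_model` trained on 27-element window vectors with
#'   classes among lesion / border_line / background.
#' @param vol an [suv_volume] (or 3D array).
#' @return A [class_maps] partition of the grid.
#' @export
classify_volume <- function(model, vol) {
  stopifnot(inherits(model, "da_model"))
  if (model$p != 27L)
    stopf("classify_volume needs a model trained on 27-element windows")
  if (!all(model$classes %in% tissue_levels))
    stopf("model classes must be tissue classes (lesion/border_line/background)")
  v <- vol_array(vol)
  d <- dim(v)
  off <- window_offsets()
  scores <- lapply(seq_along(model$classes), function(ci) array(model$b[ci], d))
  for (r in seq_len(nrow(off))) {
    shifted <- shift_arr(v, off[r, ], pad = "replicate")
    for (ci in seq_along(model$classes)) {
      w <- model$W[r, ci]
      if (w != 0) scores[[ci]] <- scores[[ci]] + w * shifted
    }
  }
  best <- array(1L, d)
  best_s <- scores[[1]]
  for (ci in seq_along(model$classes)[-1]) {
    upd <- scores[[ci]] > best_s
    best[upd] <- ci
    best_s[upd] <- scores[[ci]][upd]
  }
  cls <- model$classes
  chi <- lapply(tissue_levels, function(tl) {
    ci <- match(tl, cls)
    if (is.na(ci)) array(0, d) else (best == ci) + 0
  })
  g <- if (inherits(vol, "suv_volume")) vol$grid else grid3d(d, c(1, 1, 1))
  class_maps(chi[[1]], chi[[2]], chi[[3]], g)
}

#' Serialize / restore a trained classifier
#'
#' The model (class list, means, pooled covariance, priors, gamma, and
#' the window flattening order) is stored as JSON so a model trained once
#' can drive any number of segmentations.
#'
#' @param model a `da_model`.
#' @param path output JSON path.
#' @return `path` invisibly; `read_da_model` returns the `da_model`.
#' @export
write_da_model <- function(model, path) {
  stopifnot(inherits(model, "da_model"))
  obj <- list(classes = model$classes, means = model$means, cov = model$cov,
              gamma = model$gamma, priors = model$priors, p = model$p,
              flattening = "x-fastest (dx, then dy, then dz), offsets -1:1",
              heldout = as.list(model$heldout))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_da_model
#' @export
read_da_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- as.integer(obj$p)
  means <- matrix(as.numeric(obj$means), ncol = p)
  rownames(means) <- as.character(obj$classes)
  Sg <- matrix(as.numeric(obj$cov), p, p) + diag(obj$gamma, p)
  W <- chol2inv(chol(Sg)) %*% t(means)
  b <- -0.5 * colSums(t(means) * W) + log(as.numeric(obj$priors))
  structure(list(classes = as.character(obj$classes), means = means,
                 cov = matrix(as.numeric(obj$cov), p, p),
                 gamma = as.numeric(obj$gamma),
                 priors = as.numeric(obj$priors), W = W, b = b, p = p,
                 heldout = unlist(obj$heldout)),
            class = "da_model")
}
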