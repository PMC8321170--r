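test_that("well-separated Gaussian classes are classified nearly perfectly", {
  s <- gaussian_classes(n_per_class = 400, separation = 10, seed = 11)
  m <- da_train(s, seed = 1)
  expect_gte(m$heldout[["accuracy"]], 0.999)
  expect_gte(m$heldout[["auc"]], 0.999)
  # each class mean is classified as its own class
  pr <- da_predict(m, m$means)
  expect_identical(as.character(pr$class), m$classes)
})

test_that("model statistics are invariant to sample duplication", {
  s <- gaussian_classes(n_per_class = 60, separation = 4, seed = 5)
  dup <- structure(list(X = rbind(s$X, s$X), label = factor(c(
    as.character(s$label), as.character(s$label)),
    levels = levels(s$label))), class = "pet_samples")
  m1 <- petsurf:::fit_lda_core(s$X, s$label, gamma = 1e-8)
  m2 <- petsurf:::fit_lda_core(dup$X, dup$label, gamma = 1e-8)
  expect_equal(m1$means, m2$means, tolerance = 1e-12)
  expect_equal(m1$priors, m2$priors, tolerance = 1e-12)
  # covariance uses n - C, so duplication changes it only by (2n-C)/(n-C)
  # scaling of the same matrix shape; predictions must agree
  expect_identical(as.character(da_predict(m1, s$X)$class),
                   as.character(da_predict(m2, s$X)$class))
})

test_that("discriminant decisions are invariant under common affine rescaling", {
  s <- gaussian_classes(n_per_class = 80, separation = 3, seed = 7)
  m1 <- da_train(s, seed = 2)
  s2 <- s
  s2$X <- 3.7 * s$X + 11
  m2 <- da_train(s2, seed = 2)
  expect_identical(as.character(da_predict(m1, s$X)$class),
                   as.character(da_predict(m2, s2$X)$class))
})

test_that("predictions agree with MASS::lda on well-conditioned data", {
  skip_if_not_installed("MASS")
  s <- gaussian_classes(n_per_class = 120, separation = 2.5,
                        classes = c("lesion", "border_line", "background"),
                        seed = 13)
  m <- petsurf:::fit_lda_core(s$X, s$label, gamma = 0)
  ref <- MASS::lda(s$X, grouping = s$label)
  mine <- as.character(da_predict(m, s$X)$class)
  theirs <- as.character(predict(ref, s$X)$class)
  expect_gt(mean(mine == theirs), 0.999)
})

test_that("singular covariance without regularization gives an actionable error", {
  X <- matrix(1, 80, 27)  # constant features: zero covariance
  X[, 1] <- rep(c(0, 10), each = 40)
  y <- rep(c("background", "lesion"), each = 40)
  expect_error(petsurf:::fit_lda_core(X, y, gamma = 0), "gamma")
  expect_silent(petsurf:::fit_lda_core(X, y, gamma = 1e-6))
})

test_that("k-fold CV is deterministic, stable in k, and exact when separable", {
  s <- gaussian_classes(n_per_class = 300, separation = 10, seed = 21)
  a <- da_kfold_cv(s, k = 5, seed = 3)
  b <- da_kfold_cv(s, k = 5, seed = 3)
  expect_identical(a$folds, b$folds)
  accs <- vapply(c(5, 10, 15), function(k)
    da_kfold_cv(s, k = k, seed = 3)$mean[["accuracy"]], numeric(1))
  expect_lt(max(accs) - min(accs), 0.01)
  expect_gte(min(accs), 0.999)
  expect_error(da_kfold_cv(s, k = 10000, seed = 1), "number of samples")

  # leave-one-out on two perfectly separated points per class
  tiny <- structure(list(
    X = rbind(matrix(0, 2, 27), matrix(50, 2, 27)) +
      matrix(rnorm(4 * 27, sd = 0.01), 4, 27),
    label = factor(rep(c("background", "lesion"), each = 2))),
    class = "pet_samples")
  cv <- da_kfold_cv(tiny, k = 4, gamma = 1e-4, seed = 1) # leave-one-out
  expect_equal(cv$mean[["accuracy"]], 1.0)
})

test_that("roc_auc matches its rank definition including ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(roc_auc(c(5, 1), c(FALSE, TRUE)), 0)
  expect_equal(roc_auc(c(1, 1), c(TRUE, FALSE)), 0.5) # tie counts one half
  set.seed(99)
  sc <- rnorm(1e4)
  lb <- sample(c(TRUE, FALSE), 1e4, replace = TRUE)
  expect_lt(abs(roc_auc(sc, lb) - 0.5), 0.02)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("classify_volume partitions the grid and respects window purity", {
  ph <- tiny_sphere_phantom(c(16, 16, 14), radius = 6, noise = 0.2, seed = 8)
  s <- extract_samples(ph$volume, ph$gold)
  m <- da_train(s, seed = 4)
  maps <- classify_volume(m, ph$volume)
  expect_true(all(maps$chi_lesion + maps$chi_border + maps$chi_background == 1))

  # uniform volume: identical windows, a single class everywhere
  u <- suv_volume(array(5, c(8, 8, 8)), spacing = c(1, 1, 1))
  mu <- classify_volume(m, u)
  counts <- c(sum(mu$chi_lesion), sum(mu$chi_border), sum(mu$chi_background))
  expect_identical(sort(counts, decreasing = TRUE)[1], 512)

  # noiseless phantom: windows fully inside the gold mask are pure lesion
  ph0 <- tiny_sphere_phantom(c(16, 16, 14), radius = 6, noise = 0, seed = 8)
  s0 <- extract_samples(ph0$volume, ph0$gold)
  m0 <- da_train(s0, seed = 4)
  maps0 <- classify_volume(m0, ph0$volume)
  core <- erode_face(ph0$gold$values)
  expect_true(all(maps0$chi_lesion[core] == 1))
})

test_that("model JSON serialization round trips predictions", {
  s <- gaussian_classes(n_per_class = 100, separation = 5, seed = 31)
  m <- da_train(s, seed = 1)
  f <- tempfile(fileext = ".json")
  write_da_model(m, f)
  m2 <- read_da_model(f)
  expect_equal(m2$W, m$W, tolerance = 1e-12)
  expect_identical(as.character(da_predict(m2, s$X)$class),
                   as.character(da_predict(m, s$X)$class))
})
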