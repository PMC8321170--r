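test_that("confusion counts match a manual tally and extreme cases", {
  a <- random_mask(c(6, 6, 6), p = 0.5, seed = 41)
  b <- random_mask(c(6, 6, 6), p = 0.5, seed = 42)
  cc <- confusion_counts(a, b)
  tp <- 0; fp <- 0; fn <- 0; tn <- 0
  for (i in seq_along(a)) {
    if (a[i] == 1 && b[i] == 1) tp <- tp + 1
    else if (a[i] == 1 && b[i] == 0) fp <- fp + 1
    else if (a[i] == 0 && b[i] == 1) fn <- fn + 1
    else tn <- tn + 1
  }
  expect_identical(unname(cc), as.integer(c(tp, fp, fn, tn)))
  expect_identical(unname(sum(cc)), 216L)

  same <- confusion_counts(a, a)
  expect_identical(unname(same[c("FP", "FN")]), c(0L, 0L))
  inv <- confusion_counts(a, 1 - a)
  expect_identical(unname(inv[c("TP", "TN")]), c(0L, 0L))
})

test_that("rate formulas are exact and recomputable from counts", {
  r <- seg_rates(c(TP = 2, FP = 1, FN = 1, TN = 96))
  expect_equal(unname(r["dsc"]), 4 / 6, tolerance = 1e-12)
  expect_equal(unname(r["sensitivity"]), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(r["ppv"]), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(r["accuracy"]), 0.98, tolerance = 1e-12)
  expect_equal(unname(r["specificity"]), 96 / 97, tolerance = 1e-12)

  perfect <- seg_rates(c(TP = 50, FP = 0, FN = 0, TN = 50))
  expect_true(all(perfect == 1))

  set.seed(7)
  for (i in 1:5) {
    cc <- c(TP = sample(0:50, 1), FP = sample(0:50, 1),
            FN = sample(0:50, 1), TN = sample(1:50, 1))
    r <- seg_rates(cc)
    ref <- c(cc[["TP"]] / (cc[["TP"]] + cc[["FN"]]),
             cc[["TN"]] / (cc[["TN"]] + cc[["FP"]]),
             cc[["TP"]] / (cc[["TP"]] + cc[["FP"]]),
             (cc[["TP"]] + cc[["TN"]]) / sum(cc),
             2 * cc[["TP"]] / (2 * cc[["TP"]] + cc[["FP"]] + cc[["FN"]]))
    ref[!is.finite(ref)] <- 1
    expect_equal(unname(r)[1:5], ref, tolerance = 1e-12)
    expect_equal(unname(r["dsc"]),
                 2 * attr(r, "counts")[["TP"]] /
                   (2 * attr(r, "counts")[["TP"]] +
                      attr(r, "counts")[["FP"]] + attr(r, "counts")[["FN"]]),
                 tolerance = 1e-12)
  }
  # degenerate 0/0 convention is 1 with a flag
  dg <- seg_rates(c(TP = 0, FP = 0, FN = 0, TN = 10))
  expect_equal(unname(dg["sensitivity"]), 1)
  expect_true("sensitivity" %in% attr(dg, "degenerate"))
})

test_that("Hausdorff distance matches the all-pairs oracle and scaling law", {
  # two single voxels three apart along x
  a <- array(0, c(8, 8, 8)); a[2, 4, 4] <- 1
  b <- array(0, c(8, 8, 8)); b[5, 4, 4] <- 1
  expect_equal(hausdorff_distance(a, b), 3)
  expect_equal(hausdorff_distance(a, a), 0)

  for (seed in c(51, 52)) {
    ra <- random_mask(c(8, 8, 8), p = 0.25, seed = seed)
    rb <- random_mask(c(8, 8, 8), p = 0.25, seed = seed + 10)
    expect_equal(hausdorff_distance(ra, rb), oracle_hausdorff(ra, rb),
                 tolerance = 1e-9)
    # symmetry
    expect_equal(hausdorff_distance(ra, rb), hausdorff_distance(rb, ra))
    # isotropic mm scaling
    ma <- binary_mask(ra, spacing = c(2.5, 2.5, 2.5))
    mb <- binary_mask(rb, spacing = c(2.5, 2.5, 2.5))
    expect_equal(hausdorff_distance(ma, mb, units = "mm"),
                 2.5 * hausdorff_distance(ma, mb, units = "voxel"),
                 tolerance = 1e-9)
    # anisotropic mm mode against the oracle
    an <- binary_mask(ra, spacing = c(2.73, 2.73, 3.27))
    bn <- binary_mask(rb, spacing = c(2.73, 2.73, 3.27))
    expect_equal(hausdorff_distance(an, bn, units = "mm"),
                 oracle_hausdorff(ra, rb, c(2.73, 2.73, 3.27)),
                 tolerance = 1e-9)
  }
  expect_error(hausdorff_distance(a, array(0, c(8, 8, 8))), "non-empty")
})

test_that("dsc = 1 exactly when hd = 0 for non-empty masks", {
  m <- random_mask(c(7, 7, 7), p = 0.3, seed = 61)
  expect_equal(unname(seg_rates(confusion_counts(m, m))["dsc"]), 1)
  expect_equal(hausdorff_distance(m, m), 0)
  m2 <- m; m2[which(m2 == 0)[1]] <- 1
  expect_lt(unname(seg_rates(confusion_counts(m2, m))["dsc"]), 1)
  expect_gt(hausdorff_distance(m2, m), 0)
})

test_that("Pearson correlation matches hand-computed values", {
  expect_equal(pearson_cc(1:10, 1:10), 1)
  expect_equal(pearson_cc(1:10, -(1:10)), -1)
  expect_equal(pearson_cc(c(1, 2, 3), c(1, 2, 4)), 0.9819805, # = 1.5/sqrt(1*7/3)
               tolerance = 1e-4)
  set.seed(71)
  x <- rnorm(10); y <- rnorm(10)
  cov_xy <- sum((x - mean(x)) * (y - mean(y))) / 9
  expect_equal(pearson_cc(x, y), cov_xy / (sd(x) * sd(y)), tolerance = 1e-12)
  expect_error(pearson_cc(1:3, 1:4), "equal-length")
  expect_error(pearson_cc(c(1, 1, 1), 1:3), "zero-variance")
})

test_that("Euler characteristic and components identify solids correctly", {
  one <- array(0, c(5, 5, 5)); one[3, 3, 3] <- 1
  expect_identical(euler_characteristic(one), 1L)
  cube <- array(0, c(6, 6, 6)); cube[2:4, 2:4, 2:4] <- 1
  expect_identical(euler_characteristic(cube), 1L)
  # analytic solid torus
  d <- c(20, 20, 10)
  tor <- array(0, d)
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    tor[i, j, k] <- as.numeric((sqrt((i - 10.5)^2 + (j - 10.5)^2) - 6)^2 +
                                 (k - 5.5)^2 <= 2.5^2)
  }
  expect_identical(euler_characteristic(tor), 0L)
  expect_identical(n_components(tor), 1L)
  # two disjoint voxels: chi = 2, components = 2 (26), but 6-connectivity
  # separates diagonal neighbors
  two <- array(0, c(5, 5, 5)); two[1, 1, 1] <- 1; two[4, 4, 4] <- 1
  expect_identical(euler_characteristic(two), 2L)
  expect_identical(n_components(two), 2L)
  diagpair <- array(0, c(4, 4, 4)); diagpair[2, 2, 2] <- 1; diagpair[3, 3, 3] <- 1
  expect_identical(n_components(diagpair, connectivity = 26), 1L)
  expect_identical(n_components(diagpair, connectivity = 6), 2L)
})
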