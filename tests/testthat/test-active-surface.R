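make_maps <- function(chiL, chiB = NULL, spacing = c(1, 1, 1)) {
  d <- dim(chiL)
  if (is.null(chiB)) chiB <- 1 - chiL
  class_maps(chiL, 1 - chiL - chiB, chiB, grid3d(d, spacing))
}

test_that("prior fields are exact on uniform maps and match brute-force sums", {
  d <- c(9, 9, 9)
  all_lesion <- make_maps(array(1, d))
  pf <- prior_fields(all_lesion, l = 3)
  expect_equal(max(abs(pf$P_in - 1)), 0, tolerance = 1e-10)
  expect_equal(max(abs(pf$P_out)), 0, tolerance = 1e-10)

  # all border-line: no prior penalty anywhere
  all_border <- class_maps(array(0, d), array(1, d), array(0, d),
                           grid3d(d, c(1, 1, 1)))
  pb <- prior_fields(all_border, l = 3)
  expect_lt(max(abs(pb$P_in)) + max(abs(pb$P_out)), 1e-10)

  set.seed(23)
  lab <- array(sample(1:3, prod(d), replace = TRUE), d)
  maps <- class_maps((lab == 1) + 0, (lab == 2) + 0, (lab == 3) + 0,
                     grid3d(d, c(1, 1, 1)))
  pr <- prior_fields(maps, l = 2.5)
  for (x in list(c(5, 5, 5), c(1, 1, 1), c(9, 3, 7), c(2, 9, 4))) {
    expect_equal(pr$P_in[x[1], x[2], x[3]],
                 oracle_prior_at(maps$chi_lesion, x, 2.5), tolerance = 1e-10)
    expect_equal(pr$P_out[x[1], x[2], x[3]],
                 oracle_prior_at(maps$chi_background, x, 2.5),
                 tolerance = 1e-10)
  }
})

test_that("localized means reproduce masked averages and their exact limits", {
  d <- c(10, 10, 10)
  img <- array(1, d); img[4:7, 4:7, 4:7] <- 8
  phi <- array(1, d); phi[4:7, 4:7, 4:7] <- -1
  uv <- local_intensity_means(phi, img, c(4, 4, 4), l = 3)
  expect_equal(unname(uv), c(8, 1)) # piecewise-constant, surface on boundary

  u_img <- array(3.3, d)
  expect_equal(unname(local_intensity_means(phi, u_img, c(5, 5, 5), l = 2)),
               c(3.3, 3.3))

  set.seed(31)
  rimg <- array(rnorm(prod(d)), d)
  rphi <- array(rnorm(prod(d)), d)
  x <- c(6, 3, 8); l <- 2.2
  off <- oracle_ball_offsets(l)
  vin <- c(); vout <- c()
  for (r in seq_len(nrow(off))) {
    p <- x + off[r, ]
    if (all(p >= 1) && all(p <= d)) {
      if (rphi[p[1], p[2], p[3]] < 0) vin <- c(vin, rimg[p[1], p[2], p[3]])
      else vout <- c(vout, rimg[p[1], p[2], p[3]])
    }
  }
  expect_equal(unname(local_intensity_means(rphi, rimg, x, l)),
               c(mean(vin), mean(vout)), tolerance = 1e-12)
})

test_that("total energy vanishes in its two exact-zero regimes", {
  d <- c(10, 10, 10)
  img <- array(1, d); img[4:7, 4:7, 4:7] <- 8
  phi0 <- array(1, d); phi0[4:7, 4:7, 4:7] <- -1
  phi <- reinitialize(phi0)
  maps <- make_maps((img > 4) + 0)
  # lambda = 0, surface on the true boundary: both residuals vanish
  e0 <- total_energy(phi, img, maps, as_params(lambda = 0))
  expect_lt(abs(e0), 1e-9)
  # lambda = 1, all border-line: no prior penalty
  all_border <- class_maps(array(0, d), array(1, d), array(0, d),
                           grid3d(d, c(1, 1, 1)))
  e1 <- total_energy(phi, img, all_border, as_params(lambda = 1))
  expect_lt(abs(e1), 1e-9)
})

test_that("total energy matches the brute-force triple-loop oracle to 1e-9", {
  for (seed in 1:3) {
    set.seed(seed)
    d <- c(9, 9, 9)
    img <- array(rnorm(prod(d), 4, 2)^2 / 4, d)
    phi0 <- array(rnorm(prod(d)), d)
    phi <- reinitialize(phi0)
    lab <- array(sample(1:3, prod(d), replace = TRUE), d)
    maps <- class_maps((lab == 1) + 0, (lab == 2) + 0, (lab == 3) + 0,
                       grid3d(d, c(1, 1, 1)))
    p <- as_params(lambda = 0.3, l = 3)
    mine <- total_energy(phi, img, maps, p)
    theirs <- oracle_energy(phi, img, maps$chi_lesion, maps$chi_background,
                            lambda = 0.3, l = 3)
    expect_lt(abs(mine - theirs) / abs(theirs), 1e-9)
  }
})

test_that("evolution is stationary on a uniform image and descends correctly", {
  d <- c(12, 12, 12)
  u <- array(2, d)
  phi0 <- reinitialize(array(c(-1, 1)[1 + (slice.index(array(0, d), 1) > 6)], d))
  st <- surface_state(phi0)
  p <- as_params(lambda = 0, alpha = 0)
  st1 <- evolve_step(st, u, NULL, p)
  expect_identical(st1$phi, phi0) # zero speed everywhere

  # sign of the update: a band voxel matching the interior statistics and
  # favored by the classifier moves inside (phi decreases)
  img <- array(1, d); img[4:8, 4:8, 4:8] <- 8
  gold <- (img > 4) + 0
  maps <- make_maps(gold)
  phi <- reinitialize(array(1 - 2 * gold, d))
  stx <- evolve_step(surface_state(phi), img, maps, as_params())
  core <- img == 8 & abs(phi) < 1.4
  expect_true(all(stx$phi[core] <= phi[core] + 1e-12))
})

test_that("reinitialization anchors planes exactly and restores unit gradients", {
  d <- c(16, 16, 16)
  # axis-aligned planar SDF is an exact fixed point of the upwind scheme
  plane <- array(rep(seq_len(d[1]) - 8.3, times = d[2] * d[3]), d)
  out <- reinitialize(plane)
  expect_lt(max(abs(out - plane)), 1e-3)

  # doubling a distance field is rescaled back to unit gradient in band
  out2 <- reinitialize(2 * plane, iters = 80)
  band <- abs(plane) < 4
  expect_lt(max(abs(out2[band] - plane[band])), 0.15)

  # arbitrary smooth field: band gradient magnitude within [0.8, 1.2]
  w <- petsurf:::world_coords(grid3d(d, c(1, 1, 1)))
  blob <- sqrt((w$x - 7)^2 + (w$y - 8)^2 + (w$z - 7.5)^2) - 5
  warped <- tanh(blob / 3) * 8 # non-unit gradient, same zero set
  rw <- reinitialize(warped, iters = 80)
  gb <- abs(rw) < 3
  gx <- (petsurf:::shift_arr(rw, c(1, 0, 0), "replicate") -
           petsurf:::shift_arr(rw, c(-1, 0, 0), "replicate")) / 2
  gy <- (petsurf:::shift_arr(rw, c(0, 1, 0), "replicate") -
           petsurf:::shift_arr(rw, c(0, -1, 0), "replicate")) / 2
  gz <- (petsurf:::shift_arr(rw, c(0, 0, 1), "replicate") -
           petsurf:::shift_arr(rw, c(0, 0, -1), "replicate")) / 2
  gmag <- sqrt(gx^2 + gy^2 + gz^2)
  inner <- gb
  inner[c(1, d[1]), , ] <- FALSE; inner[, c(1, d[2]), ] <- FALSE
  inner[, , c(1, d[3])] <- FALSE
  expect_true(all(gmag[inner] > 0.8 & gmag[inner] < 1.2))
  # the zero crossing moved by less than half a voxel
  expect_true(all((rw < 0) == (warped < 0) |
                    abs(warped) < 1.0))
  expect_error(reinitialize(array(1, c(4, 4, 4))), "both signs")
})

test_that("prior-only segmentation recovers a gold-derived lesion map", {
  # the localized prior carries an inward bias of about l^2/(4R) on a
  # convex surface, so the sphere must be well resolved relative to l
  ph <- tiny_sphere_phantom(c(44, 44, 40), radius = 18, seed = 12)
  maps <- make_maps(ph$gold$values)
  ell <- fit_ellipsoid(ph$gold,
                       max_voxel = find_max_voxel(ph$volume, ph$gold))
  phi0 <- ellipsoid_to_levelset(ell, ph$volume$grid)
  seg <- suppressWarnings(
    segment_surface(ph$volume, maps, phi0, as_params(lambda = 1, alpha = 0)))
  r <- seg_rates(confusion_counts(seg$mask, ph$gold))
  expect_gte(r[["dsc"]], 0.98)
})

test_that("seeded segmentation runs are bit-reproducible", {
  ph <- tiny_sphere_phantom(c(20, 20, 16), radius = 7, noise = 0.4, seed = 14)
  s <- extract_samples(ph$volume, ph$gold)
  m <- da_train(s, seed = 2)
  maps <- classify_volume(m, ph$volume)
  roi <- roi_around(ph$gold, 3)
  ell <- fit_ellipsoid(seed_region(ph$volume, roi),
                       max_voxel = find_max_voxel(ph$volume, roi))
  phi0 <- ellipsoid_to_levelset(ell, ph$volume$grid)
  p <- as_params(max_iter = 120)
  a <- suppressWarnings(segment_surface(ph$volume, maps, phi0, p))
  b <- suppressWarnings(segment_surface(ph$volume, maps, phi0, p))
  expect_identical(a$state$phi, b$state$phi)
  expect_identical(a$history, b$history)
})

test_that("degenerate initializations are rejected", {
  d <- c(8, 8, 8)
  expect_error(segment_surface(array(1, d), NULL, array(1, d)),
               "empty interior")
})
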