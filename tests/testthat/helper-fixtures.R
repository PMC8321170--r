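# Shared fixture builders (all generated in code; no stored data).

tiny_sphere_phantom <- function(grid_shape = c(20, 20, 16), radius = 8,
                                spacing = c(1, 1, 1), noise = 0, psf = 0,
                                seed = 1) {
  generate_phantom(phantom_spec("sphere", grid_shape = grid_shape,
                                spacing = spacing,
                                geom = list(radius = radius),
                                noise_sigma = noise, psf_fwhm_mm = psf,
                                seed = seed))
}

# Two (or three) well-separated Gaussian classes in 27 dimensions.
gaussian_classes <- function(n_per_class = 500, separation = 10, sd = 1,
                             classes = c("lesion", "background"), seed = 42) {
  p <- 27
  set.seed(seed)
  X <- NULL; lab <- NULL
  for (ci in seq_along(classes)) {
    mu <- rep(0, p)
    mu[1] <- (ci - 1) * separation * sd
    X <- rbind(X, matrix(rnorm(n_per_class * p, sd = sd), n_per_class, p) +
                 matrix(mu, n_per_class, p, byrow = TRUE))
    lab <- c(lab, rep(classes[ci], n_per_class))
  }
  structure(list(X = X, label = factor(lab, levels = classes),
                 center = matrix(0L, nrow(X), 3)),
            class = "pet_samples")
}

random_mask <- function(d, p = 0.4, seed = 1) {
  set.seed(seed)
  array(runif(prod(d)) < p, d) + 0
}
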