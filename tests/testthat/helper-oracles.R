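# Independent brute-force oracles.  These deliberately share no code with
# the package internals: plain loops, direct set arithmetic.

oracle_ball_offsets <- function(l) {
  r <- ceiling(l)
  out <- NULL
  for (dz in -r:r) for (dy in -r:r) for (dx in -r:r) {
    if (dx * dx + dy * dy + dz * dz <= l * l) out <- rbind(out, c(dx, dy, dz))
  }
  out
}

# Local mean classification at one voxel by direct enumeration.
oracle_prior_at <- function(chi, x, l) {
  d <- dim(chi)
  off <- oracle_ball_offsets(l)
  num <- 0; den <- 0
  for (r in seq_len(nrow(off))) {
    p <- x + off[r, ]
    if (all(p >= 1) && all(p <= d)) {
      den <- den + 1
      num <- num + chi[p[1], p[2], p[3]]
    }
  }
  num / den
}

# Full-field triple-loop evaluation of the discrete active-surface energy:
# band voxels weighted by the smoothed Dirac delta, localized means with
# global-mean fallback for empty sides, clipped stencils at the edges.
oracle_energy <- function(phi, suv, chiL, chiB, lambda, l, eps = 1.5) {
  d <- dim(phi)
  off <- oracle_ball_offsets(l)
  inside <- phi < 0
  u_g <- if (any(inside)) mean(suv[inside]) else 0
  v_g <- if (any(!inside)) mean(suv[!inside]) else 0
  # local mean classification fields, every voxel
  Pin <- array(0, d); Pout <- array(0, d)
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    num_in <- 0; num_out <- 0; den <- 0
    for (r in seq_len(nrow(off))) {
      p <- c(i, j, k) + off[r, ]
      if (all(p >= 1) && all(p <= d)) {
        den <- den + 1
        num_in <- num_in + chiL[p[1], p[2], p[3]]
        num_out <- num_out + chiB[p[1], p[2], p[3]]
      }
    }
    Pin[i, j, k] <- num_in / den
    Pout[i, j, k] <- num_out / den
  }
  total <- 0; nband <- 0
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    ph <- phi[i, j, k]
    if (abs(ph) >= eps) next
    delta <- (1 + cos(pi * ph / eps)) / (2 * eps)
    if (delta <= 0) next
    nband <- nband + 1
    vals_in <- numeric(0); vals_out <- numeric(0)
    pri <- 0
    for (r in seq_len(nrow(off))) {
      p <- c(i, j, k) + off[r, ]
      if (any(p < 1) || any(p > d)) next
      sv <- suv[p[1], p[2], p[3]]
      if (inside[p[1], p[2], p[3]]) {
        vals_in <- c(vals_in, sv)
        pri <- pri + Pout[p[1], p[2], p[3]]
      } else {
        vals_out <- c(vals_out, sv)
        pri <- pri + Pin[p[1], p[2], p[3]]
      }
    }
    u <- if (length(vals_in) > 0) mean(vals_in) else u_g
    v <- if (length(vals_out) > 0) mean(vals_out) else v_g
    data_term <- sum((vals_in - u)^2) + sum((vals_out - v)^2)
    total <- total + delta * (lambda * pri + (1 - lambda) * data_term)
  }
  if (nband == 0) 0 else total / nband
}

# Independent recount of the three-class window tally over interior voxels.
oracle_window_counts <- function(gold) {
  d <- dim(gold)
  n_les <- 0; n_bor <- 0; n_bg <- 0
  for (k in 2:(d[3] - 1)) for (j in 2:(d[2] - 1)) for (i in 2:(d[1] - 1)) {
    cnt <- sum(gold[(i - 1):(i + 1), (j - 1):(j + 1), (k - 1):(k + 1)])
    if (cnt == 0) n_bg <- n_bg + 1
    else if (cnt <= 17) n_bor <- n_bor + 1
    else n_les <- n_les + 1
  }
  c(n_lesion = as.integer(n_les), n_border = as.integer(n_bor),
    n_background = as.integer(n_bg))
}

# Boundary voxels (face-adjacent to background or to the grid edge) by a
# direct per-voxel scan.
oracle_surface <- function(m) {
  d <- dim(m)
  out <- NULL
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    if (m[i, j, k] == 0) next
    boundary <- FALSE
    for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
      p <- c(i, j, k) + s
      if (any(p < 1) || any(p > d) || m[p[1], p[2], p[3]] == 0) {
        boundary <- TRUE
        break
      }
    }
    if (boundary) out <- rbind(out, c(i, j, k))
  }
  out
}

# All-pairs Hausdorff distance between boundary sets, optional mm scaling.
oracle_hausdorff <- function(a, b, spacing = c(1, 1, 1)) {
  A <- sweep(oracle_surface(a), 2, spacing, "*")
  B <- sweep(oracle_surface(b), 2, spacing, "*")
  dmin_ab <- vapply(seq_len(nrow(A)), function(i)
    min(sqrt(colSums((t(B) - A[i, ])^2))), numeric(1))
  dmin_ba <- vapply(seq_len(nrow(B)), function(i)
    min(sqrt(colSums((t(A) - B[i, ])^2))), numeric(1))
  max(max(dmin_ab), max(dmin_ba))
}

erode_face <- function(m) {
  d <- dim(m)
  out <- array(FALSE, d)
  for (k in 2:(d[3] - 1)) for (j in 2:(d[2] - 1)) for (i in 2:(d[1] - 1)) {
    out[i, j, k] <- m[i, j, k] != 0 && m[i - 1, j, k] != 0 &&
      m[i + 1, j, k] != 0 && m[i, j - 1, k] != 0 && m[i, j + 1, k] != 0 &&
      m[i, j, k - 1] != 0 && m[i, j, k + 1] != 0
  }
  out
}
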