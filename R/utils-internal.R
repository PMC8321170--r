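# Internal numerical utilities shared across modules: seeded evaluation,
# array shifting, and FFT-based convolution with compact symmetric kernels.

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# result[i,j,k] = a[i+s1, j+s2, k+s3]; out-of-range reads are zero-filled or
# edge-replicated.  Used for finite differences and small-window gathering.
shift_arr <- function(a, s, pad = c("zero", "replicate")) {
  pad <- match.arg(pad)
  d <- dim(a)
  idx <- lapply(1:3, function(ax) seq_len(d[ax]) + as.integer(s[ax]))
  if (pad == "replicate") {
    idx <- lapply(1:3, function(ax) pmin.int(pmax.int(idx[[ax]], 1L), d[ax]))
    return(a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE])
  }
  keep <- lapply(1:3, function(ax) idx[[ax]] >= 1L & idx[[ax]] <= d[ax])
  out <- array(0, d)
  if (all(vapply(keep, any, logical(1)))) {
    out[keep[[1]], keep[[2]], keep[[3]]] <-
      a[idx[[1]][keep[[1]]], idx[[2]][keep[[2]]], idx[[3]][keep[[3]]]]
  }
  out
}

# Smallest 7-smooth integer >= n (keeps mixed-radix FFTs fast).
next_fast_len <- function(n) {
  n <- as.integer(n)
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L, 7L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

# Plan a zero-padded linear convolution of fields of dimension `dims` with a
# centered, symmetric, odd-sized kernel.  Because the kernel is symmetric the
# result equals the correlation sum_o K(o) * a(x + o) with out-of-grid reads
# treated as zero.  If `global_sum` is TRUE the kernel covers the whole grid
# from every voxel and conv(a) is simply sum(a) everywhere.
conv_plan <- function(dims, kernel = NULL, global_sum = FALSE) {
  dims <- as.integer(dims)
  if (global_sum) {
    return(structure(list(dims = dims, global_sum = TRUE), class = "conv_plan"))
  }
  kd <- dim(kernel)
  stopifnot(length(kd) == 3L, all(kd %% 2L == 1L))
  r <- (kd - 1L) %/% 2L
  pd <- vapply(1:3, function(ax) next_fast_len(dims[ax] + kd[ax] - 1L), 1L)
  kp <- array(0, pd)
  ix <- lapply(1:3, function(ax) ((seq_len(kd[ax]) - r[ax] - 1L) %% pd[ax]) + 1L)
  kp[ix[[1]], ix[[2]], ix[[3]]] <- kernel
  structure(list(dims = dims, pd = pd, kf = stats::fft(kp), global_sum = FALSE),
            class = "conv_plan")
}

# Convolve one or two real fields in a single complex transform.
conv_exec <- function(plan, a, b = NULL) {
  d <- plan$dims
  if (isTRUE(plan$global_sum)) {
    ca <- array(sum(a), d)
    if (is.null(b)) return(list(a = ca))
    return(list(a = ca, b = array(sum(b), d)))
  }
  pd <- plan$pd
  ap <- array(0 + 0i, pd)
  if (is.null(b)) {
    ap[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- a
  } else {
    ap[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- complex(real = a, imaginary = b)
  }
  res <- stats::fft(stats::fft(ap) * plan$kf, inverse = TRUE) / prod(pd)
  res <- res[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), drop = FALSE]
  if (is.null(b)) list(a = Re(res)) else list(a = Re(res), b = Im(res))
}

# Integer offsets of the discrete ball {o : |o|_2 <= l} as an n x 3 matrix,
# ordered x-fastest, and the corresponding 0/1 kernel array.
ball_offsets <- function(l) {
  r <- as.integer(ceiling(l))
  g <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  g[g[, 1]^2 + g[, 2]^2 + g[, 3]^2 <= l^2, , drop = FALSE]
}

ball_kernel <- function(l) {
  r <- as.integer(ceiling(l))
  n <- 2L * r + 1L
  off <- seq.int(-r, r)
  d2 <- outer(outer(off^2, off^2, "+"), off^2, "+")
  array(as.numeric(d2 <= l^2), c(n, n, n))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
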