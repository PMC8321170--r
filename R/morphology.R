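neighbor_offsets <- function(connectivity = c(26, 6)) {
  connectivity <- match.arg(as.character(connectivity[1]), c("26", "6"))
  if (connectivity == "6") {
    rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
          c(0, 0, -1), c(0, 0, 1))
  } else {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  }
}

#' Label connected components of a 3D mask
#'
#' Frontier-based flood fill under 26- (default) or 6-connectivity.
#'
#' @param mask a [binary_mask] or 3D 0/1 array.
#' @param connectivity 26 (vertex-sharing) or 6 (face-sharing).
#' @return An integer array of the mask's dimensions: 0 outside, component
#'   id (1, 2, ...) inside.
#' @seealso [n_components()]
#' @export
label_components <- function(mask, connectivity = 26) {
  m <- vol_array(mask) != 0
  d <- dim(m)
  off <- neighbor_offsets(connectivity)
  lab <- array(0L, d)
  strides <- c(1L, d[1], d[1] * d[2])
  todo <- which(m)
  comp <- 0L
  while (length(todo) > 0L) {
    comp <- comp + 1L
    frontier <- todo[1L]
    lab[frontier] <- comp
    while (length(frontier) > 0L) {
      fi <- arrayInd(frontier, d)
      nbr <- lapply(seq_len(nrow(off)), function(r) {
        p <- fi + matrix(off[r, ], nrow(fi), 3, byrow = TRUE)
        ok <- p[, 1] >= 1L & p[, 1] <= d[1] & p[, 2] >= 1L & p[, 2] <= d[2] &
          p[, 3] >= 1L & p[, 3] <= d[3]
        p <- p[ok, , drop = FALSE]
        (p[, 1] - 1L) * strides[1] + (p[, 2] - 1L) * strides[2] +
          (p[, 3] - 1L) * strides[3] + 1L
      })
      nbr <- unique(unlist(nbr))
      nbr <- nbr[m[nbr] & lab[nbr] == 0L]
      lab[nbr] <- comp
      frontier <- nbr
    }
    todo <- todo[lab[todo] == 0L]
  }
  lab
}

#' Number of connected components of a mask
#'
#' @inheritParams label_components
#' @return Integer count.
#' @export
n_components <- function(mask, connectivity = 26) {
  max(label_components(mask, connectivity), 0L)
}

#' Euler characteristic of a voxel solid
#'
#' Computes the exact Euler characteristic `V - E + F - C` of the cubical
#' complex in which every mask voxel is a closed unit cube (vertices,
#' edges and faces shared between adjacent cubes are counted once).  For a
#' solid handlebody this equals `1 - genus` of its boundary surface: a
#' ball gives 1, a solid torus 0, and two disjoint balls 2.
#'
#' @inheritParams label_components
#' @return Integer Euler characteristic.
#' @export
euler_characteristic <- function(mask) {
  m <- vol_array(mask) != 0
  d <- dim(m)
  mp <- array(0, d + 2L)
  mp[1L + seq_len(d[1]), 1L + seq_len(d[2]), 1L + seq_len(d[3])] <- m
  win <- function(ax, n, s) s + seq_len(n) # index window helper
  cell_count <- function(span, shifts) {
    # span[ax]: number of cells along axis ax; shifts: list of 0/1 offset
    # combinations of voxels incident to the cell
    acc <- NULL
    for (sh in shifts) {
      blk <- mp[win(1, span[1], sh[1]), win(2, span[2], sh[2]),
                win(3, span[3], sh[3]), drop = FALSE]
      acc <- if (is.null(acc)) blk else pmax(acc, blk)
    }
    sum(acc)
  }
  combos <- function(ax_free) {
    # voxels incident to a cell: offsets 0/1 along axes where the cell is
    # a boundary between voxels, fixed offset 1 along axes it spans
    grid <- expand.grid(lapply(1:3, function(ax)
      if (ax %in% ax_free) c(0L, 1L) else 1L))
    lapply(seq_len(nrow(grid)), function(i) as.integer(grid[i, ]))
  }
  dd <- as.integer(d)
  V <- cell_count(dd + 1L, combos(1:3))
  E <- cell_count(c(dd[1], dd[2] + 1L, dd[3] + 1L), combos(2:3)) +
    cell_count(c(dd[1] + 1L, dd[2], dd[3] + 1L), combos(c(1, 3))) +
    cell_count(c(dd[1] + 1L, dd[2] + 1L, dd[3]), combos(1:2))
  F <- cell_count(c(dd[1] + 1L, dd[2], dd[3]), combos(1)) +
    cell_count(c(dd[1], dd[2] + 1L, dd[3]), combos(2)) +
    cell_count(c(dd[1], dd[2], dd[3] + 1L), combos(3))
  C <- sum(m)
  as.integer(V - E + F - C)
}
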