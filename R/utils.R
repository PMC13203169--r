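# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All stochastic operations in the package go through
# this so that a single integer seed makes a whole run reproducible.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Shift a 3D array by one voxel along `axis` (+1 or -1), filling with `fill`.
shift3 <- function(a, axis, by, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  idx_src <- idx_dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  n <- d[axis]
  if (by == 1L) {
    idx_dst[[axis]] <- 2:n
    idx_src[[axis]] <- 1:(n - 1L)
  } else {
    idx_dst[[axis]] <- 1:(n - 1L)
    idx_src[[axis]] <- 2:n
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# Logical mask of voxels in `mask` having at least one 6-neighbour outside
# `mask` (voxels beyond the grid count as outside).
boundary6 <- function(mask) {
  stopifnot(is.logical(mask) || is.numeric(mask))
  m <- mask != 0
  dim(m) <- dim(mask)
  interior <- m
  for (ax in 1:3) {
    interior <- interior & shift3(m, ax, 1L, FALSE) & shift3(m, ax, -1L, FALSE)
  }
  m & !interior
}

# Voxel-centre physical coordinates (mm) for a grid, as an n x 3 matrix.
voxel_centres <- function(grid, spacing) {
  ax <- lapply(1:3, function(k) (seq_len(grid[k]) - 0.5) * spacing[k])
  as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
}

# Single 6-connected component check for a logical mask (flood fill).
is_single_component6 <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0L) return(FALSE)
  d <- dim(mask)
  lab <- array(FALSE, d)
  queue <- idx[1]
  lab[queue] <- TRUE
  strides <- c(1L, d[1], d[1] * d[2])
  coords <- arrayInd(idx, d)
  lookup <- array(FALSE, d); lookup[idx] <- TRUE
  while (length(queue) > 0L) {
    cur <- queue
    queue <- integer(0)
    cc <- arrayInd(cur, d)
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      nb <- cc
      nb[, ax] <- nb[, ax] + s
      ok <- nb[, ax] >= 1L & nb[, ax] <= d[ax]
      if (!any(ok)) next
      lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * strides[2] + (nb[ok, 3] - 1L) * strides[3]
      new <- lin[lookup[lin] & !lab[lin]]
      if (length(new)) {
        lab[new] <- TRUE
        queue <- c(queue, new)
      }
    }
    queue <- unique(queue)
  }
  sum(lab) == length(idx)
}

# Closest pair of boundary voxels between two masks, in physical mm.
# Returns list(dist_mm, pair = 2x3 voxel indices), deterministic tie-break:
# lexicographically smallest (linear index in A, linear index in B).
closest_boundary_pair <- function(mask_a, mask_b, spacing) {
  ba <- which(boundary6(mask_a))
  bb <- which(boundary6(mask_b))
  if (length(ba) == 0L || length(bb) == 0L) stop("empty mask in closest_boundary_pair")
  d <- dim(mask_a)
  pa <- (arrayInd(ba, d) - 0.5) * rep(spacing, each = length(ba))
  pb <- (arrayInd(bb, d) - 0.5) * rep(spacing, each = length(bb))
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * tcrossprod(pa, pb)
  d2[d2 < 0] <- 0
  mn <- min(d2)
  hits <- which(d2 <= mn + 1e-12, arr.ind = TRUE)
  hits <- hits[order(ba[hits[, 1]], bb[hits[, 2]]), , drop = FALSE]
  ia <- ba[hits[1, 1]]
  ib <- bb[hits[1, 2]]
  list(dist_mm = sqrt(mn),
       pair = rbind(arrayInd(ia, d)[1, ], arrayInd(ib, d)[1, ]))
}
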