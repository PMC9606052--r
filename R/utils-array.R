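# Low-level 3D array utilities shared by segmentation, morphology and texture
# code. All arrays are indexed [i, j, k] with voxel centers at
# origin + (index - 1) * spacing (mm).

# The 13 unique 3D direction offsets (half of the 26-neighborhood).
offsets_3d_13 <- function() {
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  off <- off[!(off[, 1] == 0 & off[, 2] == 0 & off[, 3] == 0), , drop = FALSE]
  # keep one of each +/- pair: first non-zero component positive
  keep <- apply(off, 1, function(d) {
    nz <- d[d != 0]
    nz[1] > 0
  })
  unname(off[keep, , drop = FALSE])
}

# The 4 unique in-plane direction offsets (half of the 8-neighborhood),
# given as (di, dj, 0).
offsets_2d_4 <- function() {
  cbind(rbind(c(1, 0), c(0, 1), c(1, 1), c(1, -1)), 0L)
}

offsets_26 <- function() {
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  unname(off[!(off[, 1] == 0 & off[, 2] == 0 & off[, 3] == 0), , drop = FALSE])
}

offsets_6 <- function() {
  rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
}

# Paired in-bounds index matrices for one offset: for every voxel v with
# v + off also inside the grid, returns linear indices of v and v + off.
shift_pairs <- function(dims, off) {
  rng <- function(n, d) {
    if (d >= 0) list(a = seq_len(n - d), b = seq_len(n - d) + d)
    else list(a = seq_len(n + d) - d, b = seq_len(n + d))
  }
  r1 <- rng(dims[1], off[1]); r2 <- rng(dims[2], off[2]); r3 <- rng(dims[3], off[3])
  lin <- function(i, j, k) {
    outer_ij <- outer(i, (j - 1) * dims[1], "+")
    c(outer(outer_ij, (k - 1) * dims[1] * dims[2], "+"))
  }
  list(from = lin(r1$a, r2$a, r3$a), to = lin(r1$b, r2$b, r3$b))
}

# Connected-component labelling of a logical 3D array.
# connectivity: 26 (vertex), 18 unused, or 6 (face). Uses igraph components
# over the adjacency graph of TRUE voxels; labels are arbitrary until
# re-ordered by callers.
label_components_3d <- function(mask, connectivity = 26) {
  dims <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, dims)
  if (length(idx) == 0L) return(lab)
  compact <- array(0L, dims)
  compact[idx] <- seq_along(idx)
  offs <- if (connectivity == 26) offsets_3d_13() else offsets_6()[c(1, 3, 5), , drop = FALSE]
  edges <- vector("list", nrow(offs))
  for (o in seq_len(nrow(offs))) {
    sp <- shift_pairs(dims, offs[o, ])
    both <- mask[sp$from] & mask[sp$to]
    if (any(both)) {
      edges[[o]] <- cbind(compact[sp$from[both]], compact[sp$to[both]])
    }
  }
  edges <- do.call(rbind, edges)
  if (is.null(edges) || nrow(edges) == 0L) {
    lab[idx] <- seq_along(idx)
    return(lab)
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

# Zone labelling for size-zone / distance-zone matrices: connected components
# of *equal grey level*; `levels` is an integer array with NA outside the
# mask. Returns an integer array of zone ids (0 outside mask).
label_equal_level_zones <- function(levels, offs) {
  dims <- dim(levels)
  idx <- which(!is.na(levels))
  lab <- array(0L, dims)
  if (length(idx) == 0L) return(lab)
  compact <- array(0L, dims)
  compact[idx] <- seq_along(idx)
  edges <- vector("list", nrow(offs))
  for (o in seq_len(nrow(offs))) {
    sp <- shift_pairs(dims, offs[o, ])
    l1 <- levels[sp$from]; l2 <- levels[sp$to]
    both <- !is.na(l1) & !is.na(l2) & l1 == l2
    if (any(both)) edges[[o]] <- cbind(compact[sp$from[both]], compact[sp$to[both]])
  }
  edges <- do.call(rbind, edges)
  if (is.null(edges) || nrow(edges) == 0L) {
    lab[idx] <- seq_along(idx)
    return(lab)
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

# City-block distance map to the outside of `mask` (per-axis steps; within-
# slice only when `in_plane = TRUE`); border voxels get 1 and voxels on the
# array edge border the outside. Exact via separable min-plus sweeps: the
# |.|_1 kernel factorizes over axes, so one forward + backward pass per axis
# over the 0 (outside) / Inf (inside) indicator yields the metric distance.
distance_map_cityblock <- function(mask, in_plane = FALSE) {
  dims <- dim(mask)
  # pad with a one-voxel outside shell so array edges count as outside
  dp <- dims + 2L
  d <- array(0, dp)
  d[2:(dims[1] + 1), 2:(dims[2] + 1), 2:(dims[3] + 1)][mask] <- Inf
  axes <- if (in_plane) 1:2 else 1:3
  for (ax in axes) {
    n <- dp[ax]
    slab <- function(i) switch(ax, d[i, , ], d[, i, ], d[, , i])
    put <- function(i, v) {
      if (ax == 1) d[i, , ] <<- v else if (ax == 2) d[, i, ] <<- v else d[, , i] <<- v
    }
    for (i in 2:n) put(i, pmin(slab(i), slab(i - 1) + 1))
    for (i in (n - 1):1) put(i, pmin(slab(i), slab(i + 1) + 1))
  }
  out <- array(NA_integer_, dims)
  core <- d[2:(dims[1] + 1), 2:(dims[2] + 1), 2:(dims[3] + 1)]
  out[mask] <- as.integer(core[mask])
  out
}

# Separable Gaussian smoothing of a 3D array; sigma in voxels.
gaussian_smooth_3d <- function(a, sigma = 0.8) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv_axis <- function(a, axis) {
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    n <- dp[1]
    K <- matrix(0, n, n)
    for (o in -r:r) {
      ii <- which(seq_len(n) + o >= 1 & seq_len(n) + o <= n)
      K[cbind(ii, ii + o)] <- k[o + r + 1]
    }
    res <- K %*% matrix(ap, n, dp[2] * dp[3])
    aperm(array(res, dp), order(perm))
  }
  for (ax in 1:3) a <- conv_axis(a, ax)
  a
}

# Bounding box of TRUE voxels, padded by `pad` voxels, clipped to the grid.
bbox_ranges <- function(mask, pad = 0L) {
  dims <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0L) abort("cannot compute bounding box of an empty mask")
  ai <- arrayInd(idx, dims)
  lapply(1:3, function(ax) {
    lo <- max(1L, min(ai[, ax]) - pad)
    hi <- min(dims[ax], max(ai[, ax]) + pad)
    lo:hi
  })
}

# Voxel-offset table for a sphere of `volume_ml` (default 1 mL) given spacing;
# rows are integer offsets whose center-to-center distance <= sphere radius.
sphere_offsets <- function(spacing, volume_ml = 1) {
  r <- (3 * volume_ml * 1000 / (4 * pi))^(1 / 3)
  nr <- ceiling(r / spacing)
  g <- as.matrix(expand.grid(di = -nr[1]:nr[1], dj = -nr[2]:nr[2], dk = -nr[3]:nr[3]))
  d2 <- (g[, 1] * spacing[1])^2 + (g[, 2] * spacing[2])^2 + (g[, 3] * spacing[3])^2
  unname(g[d2 <= r^2, , drop = FALSE])
}

# Mean image value in a fixed sphere around each of `centers` (n x 3 index
# matrix); voxels of the sphere falling outside the grid are dropped.
sphere_mean_at <- function(data, centers, offsets) {
  dims <- dim(data)
  acc <- numeric(nrow(centers))
  cnt <- numeric(nrow(centers))
  for (o in seq_len(nrow(offsets))) {
    pi_ <- centers[, 1] + offsets[o, 1]
    pj <- centers[, 2] + offsets[o, 2]
    pk <- centers[, 3] + offsets[o, 3]
    ok <- pi_ >= 1 & pi_ <= dims[1] & pj >= 1 & pj <= dims[2] & pk >= 1 & pk <= dims[3]
    if (any(ok)) {
      v <- data[cbind(pi_[ok], pj[ok], pk[ok])]
      acc[ok] <- acc[ok] + v
      cnt[ok] <- cnt[ok] + 1
    }
  }
  acc / pmax(cnt, 1)
}
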