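# Grey-level matrix builders for the six texture families. All take an
# integer level array (`NA` outside the mask) and return raw count matrices;
# normalization happens in the feature formulas. Level arrays are assumed
# cropped to the mask bounding box by the caller.

# Symmetric grey-level co-occurrence counts for one direction offset.
glcm_counts <- function(lv, off, ng) {
  dims <- dim(lv)
  sp <- shift_pairs(dims, off)
  l1 <- lv[sp$from]; l2 <- lv[sp$to]
  ok <- !is.na(l1) & !is.na(l2)
  l1 <- l1[ok]; l2 <- l2[ok]
  cnt <- tabulate((l1 - 1L) * ng + l2, nbins = ng * ng) +
         tabulate((l2 - 1L) * ng + l1, nbins = ng * ng)
  matrix(cnt, ng, ng, byrow = TRUE)
}

# Run-length counts for one direction. Runs are maximal sequences of equal
# level along the direction; out-of-mask voxels break runs.
glrlm_counts <- function(lv, off, ng) {
  dims <- dim(lv)
  idx <- which(!is.na(lv))
  if (!length(idx)) return(matrix(0, ng, 1))
  ai <- arrayInd(idx, dims)
  lev <- lv[idx]
  t_par <- if (off[1] != 0) ai[, 1] * off[1] else if (off[2] != 0) ai[, 2] * off[2] else ai[, 3] * off[3]
  B <- max(dims) * 4 + 4
  a1 <- ai[, 1] - t_par * off[1]
  a2 <- ai[, 2] - t_par * off[2]
  a3 <- ai[, 3] - t_par * off[3]
  key <- (a1 + B) + (a2 + B) * (2 * B) + (a3 + B) * (2 * B)^2
  o <- order(key, t_par)
  key <- key[o]; t_par <- t_par[o]; lev <- lev[o]
  n <- length(o)
  newrun <- c(TRUE, key[-1] != key[-n] | t_par[-1] != t_par[-n] + 1 | lev[-1] != lev[-n])
  rid <- cumsum(newrun)
  rlen <- tabulate(rid)
  rlev <- lev[newrun]
  lmax <- max(rlen)
  m <- matrix(0, ng, lmax)
  cnt <- tabulate((rlev - 1L) * lmax + rlen, nbins = ng * lmax)
  matrix(cnt, ng, lmax, byrow = TRUE)
}

# Size-zone counts: zones are connected components of equal level
# (26-connected in 3D, 8-connected in-plane for 2D slices). Returns the
# count matrix plus the per-zone level/size/zone-id arrays for reuse by the
# distance-zone matrix.
glszm_zones <- function(lv, offs) {
  zid <- label_equal_level_zones(lv, offs)
  nz <- max(zid)
  if (nz == 0L) return(list(level = integer(0), size = integer(0), zid = zid))
  inmask <- zid > 0
  z <- zid[inmask]
  size <- tabulate(z, nbins = nz)
  level <- lv[inmask][match(seq_len(nz), z)]
  list(level = level, size = size, zid = zid)
}

glszm_counts <- function(zones, ng) {
  if (!length(zones$size)) return(matrix(0, ng, 1))
  smax <- max(zones$size)
  cnt <- tabulate((zones$level - 1L) * smax + zones$size, nbins = ng * smax)
  matrix(cnt, ng, smax, byrow = TRUE)
}

# Distance-zone counts: same zones, column = minimum city-block distance of
# the zone to the VOI border (border voxels have distance 1).
gldzm_counts <- function(zones, dmap, ng) {
  if (!length(zones$size)) return(matrix(0, ng, 1))
  inmask <- zones$zid > 0
  z <- zones$zid[inmask]
  dv <- dmap[inmask]
  mind <- as.integer(tapply(dv, z, min))
  dmax <- max(mind)
  cnt <- tabulate((zones$level - 1L) * dmax + mind, nbins = ng * dmax)
  matrix(cnt, ng, dmax, byrow = TRUE)
}

# Neighborhood grey-tone difference sums: for each level i, the total
# absolute difference between voxel level and the mean of its valid
# neighbors, plus the voxel count per level. `offs` is the full
# neighborhood (26 offsets in 3D, 8 in-plane in 2D).
ngtdm_stats <- function(lv, offs, ng) {
  dims <- dim(lv)
  msk <- !is.na(lv)
  lvz <- lv; lvz[!msk] <- 0L
  nb_sum <- array(0, dims); nb_cnt <- array(0, dims)
  for (o in seq_len(nrow(offs))) {
    sp <- shift_pairs(dims, offs[o, ])
    valid <- msk[sp$to]
    from <- sp$from[valid]
    nb_sum[from] <- nb_sum[from] + lvz[sp$to[valid]]
    nb_cnt[from] <- nb_cnt[from] + 1
  }
  use <- msk & nb_cnt > 0
  if (!any(use)) return(list(s = numeric(ng), n = numeric(ng)))
  dev <- abs(lv[use] - nb_sum[use] / nb_cnt[use])
  levu <- lv[use]
  s <- numeric(ng); nn <- numeric(ng)
  agg <- rowsum(dev, levu)
  s[as.integer(rownames(agg))] <- agg[, 1]
  tab <- tabulate(levu, nbins = ng)
  list(s = s, n = as.numeric(tab))
}

# Neighboring grey-level dependence counts with coarseness alpha = 0:
# dependence count k = number of neighbors with the same level; matrix
# column index is k + 1.
ngldm_counts <- function(lv, offs, ng) {
  dims <- dim(lv)
  msk <- !is.na(lv)
  if (!any(msk)) return(matrix(0, ng, 1))
  dep <- array(0L, dims)
  for (o in seq_len(nrow(offs))) {
    sp <- shift_pairs(dims, offs[o, ])
    eq <- msk[sp$from] & msk[sp$to] & lv[sp$from] == lv[sp$to]
    eq[is.na(eq)] <- FALSE
    from <- sp$from[eq]
    dep[from] <- dep[from] + 1L
  }
  j <- dep[msk] + 1L
  lev <- lv[msk]
  kmax <- max(j)
  cnt <- tabulate((lev - 1L) * kmax + j, nbins = ng * kmax)
  matrix(cnt, ng, kmax, byrow = TRUE)
}
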