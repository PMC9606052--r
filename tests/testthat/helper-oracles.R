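# Brute-force enumeration oracles for the texture matrix families and for
# connected-component labelling. Written as plain nested loops, independent
# of the vectorized implementations they check.

oracle_glcm <- function(lv, off, ng) {
  d <- dim(lv)
  M <- matrix(0, ng, ng)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    a <- lv[i, j, k]
    if (is.na(a)) next
    for (s in c(1, -1)) {
      ii <- i + s * off[1]; jj <- j + s * off[2]; kk <- k + s * off[3]
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3]) next
      b <- lv[ii, jj, kk]
      if (!is.na(b)) M[a, b] <- M[a, b] + 1
    }
  }
  M
}

oracle_glrlm <- function(lv, off, ng) {
  d <- dim(lv)
  runs <- list()
  inb <- function(p) all(p >= 1) && all(p <= d)
  val <- function(p) lv[p[1], p[2], p[3]]
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    p <- c(i, j, k)
    v <- val(p)
    if (is.na(v)) next
    prev <- p - off
    if (inb(prev) && !is.na(val(prev)) && val(prev) == v) next  # not a run start
    len <- 1
    nxt <- p + off
    while (inb(nxt) && !is.na(val(nxt)) && val(nxt) == v) {
      len <- len + 1
      nxt <- nxt + off
    }
    runs[[length(runs) + 1]] <- c(v, len)
  }
  if (!length(runs)) return(matrix(0, ng, 1))
  rm_ <- do.call(rbind, runs)
  M <- matrix(0, ng, max(rm_[, 2]))
  for (r in seq_len(nrow(rm_))) M[rm_[r, 1], rm_[r, 2]] <- M[rm_[r, 1], rm_[r, 2]] + 1
  M
}

# queue flood fill over equal-level voxels; offs = full neighbor list
oracle_zone_label <- function(lv, offs) {
  d <- dim(lv)
  lab <- array(0L, d)
  nextlab <- 0L
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (is.na(lv[i, j, k]) || lab[i, j, k] > 0) next
    nextlab <- nextlab + 1L
    queue <- list(c(i, j, k))
    lab[i, j, k] <- nextlab
    v <- lv[i, j, k]
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (o in seq_len(nrow(offs))) {
        q <- p + offs[o, ]
        if (any(q < 1) || any(q > d)) next
        if (!is.na(lv[q[1], q[2], q[3]]) && lv[q[1], q[2], q[3]] == v &&
            lab[q[1], q[2], q[3]] == 0L) {
          lab[q[1], q[2], q[3]] <- nextlab
          queue[[length(queue) + 1]] <- q
        }
      }
    }
  }
  lab
}

oracle_glszm <- function(lv, offs, ng) {
  lab <- oracle_zone_label(lv, offs)
  nz <- max(lab)
  if (nz == 0) return(matrix(0, ng, 1))
  sizes <- integer(nz); levels <- integer(nz)
  for (z in seq_len(nz)) {
    idx <- which(lab == z)
    sizes[z] <- length(idx)
    levels[z] <- lv[idx[1]]
  }
  M <- matrix(0, ng, max(sizes))
  for (z in seq_len(nz)) M[levels[z], sizes[z]] <- M[levels[z], sizes[z]] + 1
  M
}

# city-block distance to the outside of the mask (border voxel = 1): direct
# minimum over all outside positions, including beyond the array edges
oracle_distance_map <- function(mask, in_plane = FALSE) {
  d <- dim(mask)
  dm <- array(NA_integer_, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (!mask[i, j, k]) next
    # distance to the grid boundary (stepping off the array is "outside")
    best <- min(i, d[1] + 1 - i, j, d[2] + 1 - j,
                if (in_plane) Inf else min(k, d[3] + 1 - k))
    for (ii in 1:d[1]) for (jj in 1:d[2]) {
      kks <- if (in_plane) k else 1:d[3]
      for (kk in kks) {
        if (!mask[ii, jj, kk]) {
          best <- min(best, abs(i - ii) + abs(j - jj) + abs(k - kk) )
        }
      }
    }
    dm[i, j, k] <- as.integer(best)
  }
  dm
}

oracle_gldzm <- function(lv, offs_zone, ng, in_plane = FALSE) {
  lab <- oracle_zone_label(lv, offs_zone)
  mask <- !is.na(lv)
  dm <- oracle_distance_map(mask, in_plane = in_plane)
  nz <- max(lab)
  if (nz == 0) return(matrix(0, ng, 1))
  mind <- integer(nz); levels <- integer(nz)
  for (z in seq_len(nz)) {
    idx <- which(lab == z)
    mind[z] <- min(dm[idx])
    levels[z] <- lv[idx[1]]
  }
  M <- matrix(0, ng, max(mind))
  for (z in seq_len(nz)) M[levels[z], mind[z]] <- M[levels[z], mind[z]] + 1
  M
}

oracle_ngtdm <- function(lv, offs, ng) {
  d <- dim(lv)
  s <- numeric(ng); n <- numeric(ng)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    v <- lv[i, j, k]
    if (is.na(v)) next
    nb <- c()
    for (o in seq_len(nrow(offs))) {
      q <- c(i, j, k) + offs[o, ]
      if (any(q < 1) || any(q > d)) next
      w <- lv[q[1], q[2], q[3]]
      if (!is.na(w)) nb <- c(nb, w)
    }
    if (!length(nb)) next
    s[v] <- s[v] + abs(v - mean(nb))
    n[v] <- n[v] + 1
  }
  list(s = s, n = n)
}

oracle_ngldm <- function(lv, offs, ng) {
  d <- dim(lv)
  recs <- list()
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    v <- lv[i, j, k]
    if (is.na(v)) next
    dep <- 0L
    for (o in seq_len(nrow(offs))) {
      q <- c(i, j, k) + offs[o, ]
      if (any(q < 1) || any(q > d)) next
      w <- lv[q[1], q[2], q[3]]
      if (!is.na(w) && w == v) dep <- dep + 1L
    }
    recs[[length(recs) + 1]] <- c(v, dep + 1L)
  }
  rm_ <- do.call(rbind, recs)
  M <- matrix(0, ng, max(rm_[, 2]))
  for (r in seq_len(nrow(rm_))) M[rm_[r, 1], rm_[r, 2]] <- M[rm_[r, 1], rm_[r, 2]] + 1
  M
}

# full neighbor offset lists for the oracles
oracle_offs_26 <- function() {
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  unname(off[rowSums(abs(off)) > 0, , drop = FALSE])
}
oracle_offs_8 <- function() {
  off <- as.matrix(expand.grid(-1:1, -1:1, 0))
  unname(off[rowSums(abs(off[, 1:2])) > 0, , drop = FALSE])
}
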