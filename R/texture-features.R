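# Texture feature formulas and the 408-feature panel assembly.
#
# Panel layout (family x features x aggregations):
#   GLCM  25 x {2d_avg, 2d_mrg, 25d_dmrg, 25d_mrg, 3d_avg, 3d_mrg} = 150
#   GLRLM 16 x same 6                                              =  96
#   GLSZM 16 x {2d, 25d, 3d}                                       =  48
#   GLDZM 16 x {2d, 25d, 3d}                                       =  48
#   NGTDM  5 x {2d, 25d, 3d}                                       =  15
#   NGLDM 17 x {2d, 25d, 3d}                                       =  51
#                                                            total = 408

# the run-length evaluator doubles for all run-length-style families
glrlm_eval <- function(S, nv_eff) rl_eval(S, nv_eff)

glcm_feature_names <- function() c(
  "joint_max", "joint_avg", "joint_var", "joint_entropy",
  "diff_avg", "diff_var", "diff_entropy",
  "sum_avg", "sum_var", "sum_entropy",
  "energy", "contrast", "dissimilarity",
  "inv_diff", "inv_diff_norm", "inv_diff_mom", "inv_diff_mom_norm",
  "inv_var", "correlation", "autocorrelation",
  "cluster_tendency", "cluster_shade", "cluster_prominence",
  "info_corr_1", "info_corr_2")

glrlm_feature_names <- function() c(
  "sre", "lre", "lgre", "hgre", "srlge", "srhge", "lrlge", "lrhge",
  "glnu", "glnu_norm", "rlnu", "rlnu_norm", "run_pct",
  "gl_var", "rl_var", "run_entropy")

glszm_feature_names <- function() c(
  "sze", "lze", "lgze", "hgze", "szlge", "szhge", "lzlge", "lzhge",
  "glnu", "glnu_norm", "zsnu", "zsnu_norm", "zone_pct",
  "gl_var", "zs_var", "zs_entropy")

gldzm_feature_names <- function() c(
  "sde", "lde", "lgze", "hgze", "sdlge", "sdhge", "ldlge", "ldhge",
  "glnu", "glnu_norm", "zdnu", "zdnu_norm", "zone_pct",
  "gl_var", "zd_var", "zd_entropy")

ngtdm_feature_names <- function() c(
  "coarseness", "contrast", "busyness", "complexity", "strength")

ngldm_feature_names <- function() c(
  "lde", "hde", "lgce", "hgce", "ldlge", "ldhge", "hdlge", "hdhge",
  "glnu", "glnu_norm", "dcnu", "dcnu_norm", "dc_pct",
  "gl_var", "dc_var", "dc_entropy", "dc_energy")

#' Texture panel configuration
#'
#' Describes the pinned 408-feature texture panel: per-family feature lists
#' and matrix aggregation methods (GLCM distance is 1 in Chebyshev norm).
#'
#' @return A list with one element per family giving `features` and
#'   `aggregations`; total feature count is asserted to be 408.
#' @export
texture_panel <- function() {
  aggs6 <- c("2d_avg", "2d_mrg", "25d_dmrg", "25d_mrg", "3d_avg", "3d_mrg")
  aggs3 <- c("2d", "25d", "3d")
  panel <- list(
    glcm = list(features = glcm_feature_names(), aggregations = aggs6),
    glrlm = list(features = glrlm_feature_names(), aggregations = aggs6),
    glszm = list(features = glszm_feature_names(), aggregations = aggs3),
    gldzm = list(features = gldzm_feature_names(), aggregations = aggs3),
    ngtdm = list(features = ngtdm_feature_names(), aggregations = aggs3),
    ngldm = list(features = ngldm_feature_names(), aggregations = aggs3)
  )
  total <- sum(vapply(panel, function(f) length(f$features) * length(f$aggregations),
                      numeric(1)))
  stopifnot(total == 408)
  panel
}

# ---- formula evaluators (take raw count matrices) --------------------------

# per-grey-level-count index cache: cell index vectors and grouped
# permutations for the difference (|i-j|) and sum (i+j) distributions, so
# repeated evaluations at the same ng reuse them
.glcm_cache <- new.env(parent = emptyenv())

glcm_index <- function(ng) {
  key <- as.character(ng)
  cached <- .glcm_cache[[key]]
  if (!is.null(cached)) return(cached)
  i <- rep(seq_len(ng), times = ng)
  j <- rep(seq_len(ng), each = ng)
  dk <- abs(i - j); sk <- i + j
  ord_d <- order(dk); ord_s <- order(sk)
  w_invvar <- numeric(length(dk))
  w_invvar[dk > 0] <- 1 / dk[dk > 0]^2
  idx <- list(
    i = i, j = j, dk = dk, sk = sk,
    ord_d = ord_d, bounds_d = cumsum(tabulate(dk + 1L, nbins = ng)),
    kd = 0:(ng - 1),
    ord_s = ord_s, bounds_s = cumsum(tabulate(sk - 1L, nbins = 2 * ng - 1)),
    ks = 2:(2 * ng),
    w_invd = 1 / (1 + dk), w_invdn = 1 / (1 + dk / ng),
    w_invm = 1 / (1 + dk^2), w_invmn = 1 / (1 + dk^2 / ng^2),
    w_invvar = w_invvar
  )
  .glcm_cache[[key]] <- idx
  idx
}

glcm_eval <- function(C) {
  s <- sum(C)
  ng <- nrow(C)
  p <- as.vector(C) / s
  ix <- glcm_index(ng)
  i <- ix$i; j <- ix$j
  pm <- matrix(p, ng, ng)
  pi_ <- rowSums(pm)                      # symmetric matrix: row = col marginal
  mu <- sum(i * p)
  joint_var <- sum((i - mu)^2 * p)
  pp <- p[p > 0]
  joint_entropy <- -sum(pp * log2(pp))
  # grouped distributions via one cumulative pass over the cached ordering
  cs_d <- cumsum(p[ix$ord_d])
  pd <- diff(c(0, cs_d[ix$bounds_d]))
  kd <- ix$kd
  diff_avg <- sum(kd * pd)
  diff_var <- sum((kd - diff_avg)^2 * pd)
  pdp <- pd[pd > 0]
  diff_entropy <- -sum(pdp * log2(pdp))
  cs_s <- cumsum(p[ix$ord_s])
  ps <- diff(c(0, cs_s[ix$bounds_s]))
  ks <- ix$ks
  sum_avg <- sum(ks * ps)
  sum_var <- sum((ks - sum_avg)^2 * ps)
  psp <- ps[ps > 0]
  sum_entropy <- -sum(psp * log2(psp))
  energy <- sum(p^2)
  contrast <- sum(ix$dk^2 * p)
  dissim <- sum(ix$dk * p)
  inv_diff <- sum(p * ix$w_invd)
  inv_diff_norm <- sum(p * ix$w_invdn)
  inv_diff_mom <- sum(p * ix$w_invm)
  inv_diff_mom_norm <- sum(p * ix$w_invmn)
  inv_var <- sum(p * ix$w_invvar)
  correlation <- if (joint_var > 0) (sum(i * j * p) - mu^2) / joint_var else 1
  autocorr <- sum(i * j * p)
  ij2mu <- i + j - 2 * mu
  ct <- sum(ij2mu^2 * p)
  cs2 <- sum(ij2mu^3 * p)
  cp <- sum(ij2mu^4 * p)
  # information correlations
  hx <- { q <- pi_[pi_ > 0]; -sum(q * log2(q)) }
  pij_ind <- pi_[i] * pi_[j]
  sel <- p > 0 & pij_ind > 0
  hxy1 <- -sum(p[sel] * log2(pij_ind[sel]))
  selk <- pij_ind > 0
  hxy2 <- -sum(pij_ind[selk] * log2(pij_ind[selk]))
  ic1 <- if (hx > 0) (joint_entropy - hxy1) / hx else 0
  ic2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - joint_entropy))))
  c(max(p), mu, joint_var, joint_entropy, diff_avg, diff_var, diff_entropy,
    sum_avg, sum_var, sum_entropy, energy, contrast, dissim,
    inv_diff, inv_diff_norm, inv_diff_mom, inv_diff_mom_norm,
    inv_var, correlation, autocorr, ct, cs2, cp, ic1, ic2)
}

# Shared formulas for the run-length-style families (GLRLM / GLSZM / GLDZM):
# counts over (grey level i, second axis j); `nv_eff` is the voxel count
# (times the number of merged directions for GLRLM) for the percentage
# feature.
rl_eval <- function(S, nv_eff) {
  ns <- sum(S)
  p <- S / ns
  i <- row(p); j <- col(p)
  ri <- rowSums(S); cj <- colSums(S)
  jv <- seq_len(ncol(S)); iv <- seq_len(nrow(S))
  sre <- sum(t(cj / jv^2)) / ns
  lre <- sum(cj * jv^2) / ns
  lgre <- sum(ri / iv^2) / ns
  hgre <- sum(ri * iv^2) / ns
  srlge <- sum(S / (i^2 * j^2)) / ns
  srhge <- sum(S * i^2 / j^2) / ns
  lrlge <- sum(S * j^2 / i^2) / ns
  lrhge <- sum(S * i^2 * j^2) / ns
  glnu <- sum(ri^2) / ns
  glnu_n <- sum(ri^2) / ns^2
  rlnu <- sum(cj^2) / ns
  rlnu_n <- sum(cj^2) / ns^2
  rp <- ns / nv_eff
  mu_i <- sum(i * p); gl_var <- sum((i - mu_i)^2 * p)
  mu_j <- sum(j * p); rl_var <- sum((j - mu_j)^2 * p)
  pp <- p[p > 0]
  rent <- -sum(pp * log2(pp))
  c(sre, lre, lgre, hgre, srlge, srhge, lrlge, lrhge,
    glnu, glnu_n, rlnu, rlnu_n, rp, gl_var, rl_var, rent)
}

ngtdm_eval <- function(st, ng) {
  nn <- st$n; s <- st$s
  N <- sum(nn)
  if (N == 0) return(c(1e6, 0, 0, 0, 0))
  p <- nn / N
  pres <- which(p > 0)
  ngp <- length(pres)
  denom_c <- sum(p * s)
  coarse <- if (denom_c > 0) min(1 / denom_c, 1e6) else 1e6
  if (ngp > 1) {
    ii <- pres
    pd <- p[pres]
    dif2 <- outer(ii, ii, function(a, b) (a - b)^2)
    contrast <- (sum(outer(pd, pd) * dif2) / (ngp * (ngp - 1))) * (sum(s) / N)
    ipij <- abs(outer(ii * pd, ii * pd, "-"))
    denom_b <- sum(ipij)
    busy <- if (denom_b > 0) denom_c / denom_b else 0
    num_cx <- outer(pd * s[pres], pd * s[pres], "+")
    den_cx <- outer(pd, pd, "+")
    cx <- sum(abs(outer(ii, ii, "-")) * num_cx / den_cx) / N
    den_st <- sum(s)
    strength <- if (den_st > 0) sum(outer(pd, pd, "+") * dif2) / den_st else 0
  } else {
    contrast <- 0; busy <- 0; cx <- 0; strength <- 0
  }
  c(coarse, contrast, busy, cx, strength)
}

ngldm_eval <- function(D) {
  ns <- sum(D)
  p <- D / ns
  i <- row(p); j <- col(p)
  ri <- rowSums(D); cj <- colSums(D)
  iv <- seq_len(nrow(D)); jv <- seq_len(ncol(D))
  lde <- sum(cj / jv^2) / ns
  hde <- sum(cj * jv^2) / ns
  lgce <- sum(ri / iv^2) / ns
  hgce <- sum(ri * iv^2) / ns
  ldlge <- sum(D / (i^2 * j^2)) / ns
  ldhge <- sum(D * i^2 / j^2) / ns
  hdlge <- sum(D * j^2 / i^2) / ns
  hdhge <- sum(D * i^2 * j^2) / ns
  glnu <- sum(ri^2) / ns
  glnu_n <- sum(ri^2) / ns^2
  dcnu <- sum(cj^2) / ns
  dcnu_n <- sum(cj^2) / ns^2
  dcp <- 1   # every in-mask voxel contributes one dependence count
  mu_i <- sum(i * p); gl_var <- sum((i - mu_i)^2 * p)
  mu_j <- sum(j * p); dc_var <- sum((j - mu_j)^2 * p)
  pp <- p[p > 0]
  dce <- -sum(pp * log2(pp))
  dc_energy <- sum(p^2)
  c(lde, hde, lgce, hgce, ldlge, ldhge, hdlge, hdhge,
    glnu, glnu_n, dcnu, dcnu_n, dcp, gl_var, dc_var, dce, dc_energy)
}

# ---- aggregation assembly --------------------------------------------------

pad_cols <- function(m, nc) {
  if (ncol(m) >= nc) m else cbind(m, matrix(0, nrow(m), nc - ncol(m)))
}

sum_mats <- function(mats) {
  nc <- max(vapply(mats, ncol, integer(1)))
  Reduce(`+`, lapply(mats, pad_cols, nc = nc))
}

#' Texture features of a discretized volume
#'
#' Computes all 408 texture features (see [texture_panel()]). Matrices are
#' built per slice and per direction as required by each aggregation method;
#' single-level regions take their analytic degenerate values (e.g. GLCM
#' joint entropy 0) rather than `NaN`.
#'
#' @param disc A [discretize()] result.
#' @return A one-row tibble with 408 `tex_*` columns.
#' @export
texture_features <- function(disc) {
  stopifnot(inherits(disc, "discretized_volume"))
  rng <- bbox_ranges(disc$mask, pad = 0L)
  lv <- disc$levels[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  if (length(dim(lv)) < 3) lv <- array(lv, c(length(rng[[1]]), length(rng[[2]]), length(rng[[3]])))
  ng <- disc$n_levels
  msk <- !is.na(lv)
  nv <- sum(msk)
  lv_first <- lv[msk][1]
  zs <- which(apply(msk, 3, any))
  dirs3 <- offsets_3d_13()
  dirs2 <- offsets_2d_4()
  n3 <- nrow(dirs3); n2 <- nrow(dirs2)
  slice_of <- function(z) {
    s <- lv[, , z, drop = FALSE]
    array(s, c(dim(lv)[1], dim(lv)[2], 1))
  }
  nv_slice <- vapply(zs, function(z) sum(msk[, , z]), numeric(1))

  out <- list()

  # ---- GLCM / GLRLM (6 aggregations) ----
  degen_sq <- function() { m <- matrix(0, ng, ng); m[lv_first, lv_first] <- 1; m }
  degen_run <- function() { m <- matrix(0, ng, 1); m[lv_first, 1] <- nv; m }

  for (fam in c("glcm", "glrlm")) {
    build <- if (fam == "glcm") function(a, d) glcm_counts(a, d, ng)
             else function(a, d) glrlm_counts(a, d, ng)
    fn <- if (fam == "glcm") glcm_feature_names() else glrlm_feature_names()
    # per-slice, per-direction matrices
    mats <- list()   # indexed [slice][dir]
    for (si in seq_along(zs)) {
      sl <- slice_of(zs[si])
      mats[[si]] <- lapply(seq_len(n2), function(d) build(sl, dirs2[d, ]))
    }
    mats3 <- lapply(seq_len(n3), function(d) build(lv, dirs3[d, ]))

    dg <- if (fam == "glcm") degen_sq else degen_run
    eval_set <- function(mat_list, nv_eff_list, degen_nv) {
      ok <- which(vapply(mat_list, sum, numeric(1)) > 0)
      if (!length(ok)) {
        return(if (fam == "glcm") glcm_eval(dg()) else glrlm_eval(dg(), degen_nv))
      }
      vecs <- vapply(ok, function(ii) {
        if (fam == "glcm") glcm_eval(mat_list[[ii]])
        else glrlm_eval(mat_list[[ii]], nv_eff_list[[ii]])
      }, numeric(length(fn)))
      rowMeans(vecs)
    }
    flat <- unlist(mats, recursive = FALSE)
    flat_nv <- rep(nv_slice, each = n2)
    v_2d_avg <- eval_set(flat, as.list(flat_nv), nv)
    slice_merged <- lapply(seq_along(zs), function(si) sum_mats(mats[[si]]))
    v_2d_mrg <- eval_set(slice_merged, as.list(nv_slice * n2), nv * n2)
    dir_merged <- lapply(seq_len(n2), function(d) sum_mats(lapply(mats, `[[`, d)))
    v_25d_dmrg <- eval_set(dir_merged, as.list(rep(nv, n2)), nv)
    all_merged <- list(sum_mats(dir_merged))
    v_25d_mrg <- eval_set(all_merged, list(nv * n2), nv * n2)
    v_3d_avg <- eval_set(mats3, as.list(rep(nv, n3)), nv)
    v_3d_mrg <- eval_set(list(sum_mats(mats3)), list(nv * n3), nv * n3)

    vals <- c(v_2d_avg, v_2d_mrg, v_25d_dmrg, v_25d_mrg, v_3d_avg, v_3d_mrg)
    aggs <- c("2d_avg", "2d_mrg", "25d_dmrg", "25d_mrg", "3d_avg", "3d_mrg")
    nms <- as.vector(vapply(aggs, function(a) paste0("tex_", fam, "_", fn, "_", a),
                            character(length(fn))))
    out[[fam]] <- setNames(vals, nms)
  }

  # ---- GLSZM / GLDZM (2d, 25d, 3d) ----
  fn_szm <- glszm_feature_names(); fn_dzm <- gldzm_feature_names()
  zones3 <- glszm_zones(lv, dirs3)
  dmap3 <- distance_map_cityblock(msk, in_plane = FALSE)
  zones2 <- lapply(zs, function(z) glszm_zones(slice_of(z), dirs2))
  dmap2 <- lapply(zs, function(z) {
    m2 <- msk[, , z, drop = FALSE]
    distance_map_cityblock(array(m2, dim(m2)), in_plane = TRUE)
  })
  szm2 <- lapply(zones2, glszm_counts, ng = ng)
  dzm2 <- lapply(seq_along(zs), function(si) gldzm_counts(zones2[[si]], dmap2[[si]], ng))
  szm3 <- glszm_counts(zones3, ng)
  dzm3 <- gldzm_counts(zones3, dmap3, ng)

  zone_eval_set <- function(mat_list, nv_list, degen_nv) {
    ok <- which(vapply(mat_list, sum, numeric(1)) > 0)
    if (!length(ok)) return(rl_eval(degen_run(), degen_nv))
    rowMeans(vapply(ok, function(ii) rl_eval(mat_list[[ii]], nv_list[[ii]]),
                    numeric(16)))
  }
  for (fam in c("glszm", "gldzm")) {
    m2 <- if (fam == "glszm") szm2 else dzm2
    m3 <- if (fam == "glszm") szm3 else dzm3
    fn <- if (fam == "glszm") fn_szm else fn_dzm
    v_2d <- zone_eval_set(m2, as.list(nv_slice), nv)
    v_25d <- zone_eval_set(list(sum_mats(m2)), list(nv), nv)
    v_3d <- zone_eval_set(list(m3), list(nv), nv)
    vals <- c(v_2d, v_25d, v_3d)
    nms <- as.vector(vapply(c("2d", "25d", "3d"),
                            function(a) paste0("tex_", fam, "_", fn, "_", a),
                            character(length(fn))))
    out[[fam]] <- setNames(vals, nms)
  }

  # ---- NGTDM ----
  offs26 <- offsets_26()
  offs8 <- rbind(dirs2, -dirs2)
  st2 <- lapply(zs, function(z) ngtdm_stats(slice_of(z), offs8, ng))
  st3 <- ngtdm_stats(lv, offs26, ng)
  st_sum <- list(s = Reduce(`+`, lapply(st2, `[[`, "s")),
                 n = Reduce(`+`, lapply(st2, `[[`, "n")))
  ok2 <- Filter(function(s) sum(s$n) > 0, st2)
  v_2d <- if (length(ok2)) rowMeans(vapply(ok2, ngtdm_eval, numeric(5), ng = ng))
          else ngtdm_eval(st3, ng)
  v_25d <- ngtdm_eval(st_sum, ng)
  v_3d <- ngtdm_eval(st3, ng)
  fn <- ngtdm_feature_names()
  out$ngtdm <- setNames(c(v_2d, v_25d, v_3d),
                        as.vector(vapply(c("2d", "25d", "3d"),
                                         function(a) paste0("tex_ngtdm_", fn, "_", a),
                                         character(5))))

  # ---- NGLDM ----
  nd2 <- lapply(zs, function(z) ngldm_counts(slice_of(z), offs8, ng))
  nd3 <- ngldm_counts(lv, offs26, ng)
  fn <- ngldm_feature_names()
  ev_set <- function(mlist) {
    ok <- which(vapply(mlist, sum, numeric(1)) > 0)
    rowMeans(vapply(ok, function(ii) ngldm_eval(mlist[[ii]]), numeric(17)))
  }
  v_2d <- ev_set(nd2)
  v_25d <- ngldm_eval(sum_mats(nd2))
  v_3d <- ngldm_eval(nd3)
  out$ngldm <- setNames(c(v_2d, v_25d, v_3d),
                        as.vector(vapply(c("2d", "25d", "3d"),
                                         function(a) paste0("tex_ngldm_", fn, "_", a),
                                         character(17))))

  vals <- unlist(out, use.names = TRUE)
  names(vals) <- sub("^[a-z]+\\.", "", names(vals))
  stopifnot(length(vals) == 408, !anyNA(vals), all(is.finite(vals)))
  as_tibble(as.list(vals))
}
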