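#' Intensity features of a VOI
#'
#' The 50-feature intensity panel: 2 local-intensity features (local and
#' global intensity peak, 1-mL sphere means on the resampled grid), 18
#' first-order statistics of the in-mask SUVs, 23 intensity-histogram
#' features on the discretized grey levels, and 7 intensity-volume-histogram
#' (IVH) features on the continuous SUVs. Degenerate (constant) regions
#' yield defined values (variance 0, entropy 0, uniformity 1), never `NaN`.
#'
#' @param volume A [resample_volume()] result.
#' @param disc The matching [discretize()] result.
#' @return A one-row tibble with 50 `int_*` columns.
#' @export
intensity_features <- function(volume, disc) {
  stopifnot(inherits(volume, "resampled_volume"), inherits(disc, "discretized_volume"))
  x <- volume$data[volume$mask]
  n <- length(x)
  if (n < 1) abort("empty mask")

  # ---- local intensity (2) ----
  ai <- arrayInd(which(volume$mask), dim(volume$mask))
  offs <- sphere_offsets(volume$spacing, 1)
  peaks <- sphere_mean_at(volume$data, ai, offs)
  global_peak <- max(peaks)
  maxv <- max(x)
  local_peak <- max(peaks[x == maxv])   # ties: highest local mean

  # ---- intensity statistics (18) ----
  mu <- mean(x)
  vr <- mean((x - mu)^2)                      # population variance
  sdev <- sqrt(vr)
  skew <- if (sdev > 0) mean((x - mu)^3) / sdev^3 else 0
  kurt <- if (sdev > 0) mean((x - mu)^4) / sdev^4 - 3 else 0
  med <- median(x)
  q <- quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE)
  p10 <- q[1]; p25 <- q[2]; p75 <- q[3]; p90 <- q[4]
  iqr <- p75 - p25
  rng <- maxv - min(x)
  mad_mean <- mean(abs(x - mu))
  inb <- x[x >= p10 & x <= p90]
  rmad <- if (length(inb)) mean(abs(inb - mean(inb))) else 0
  medad <- mean(abs(x - med))
  cov_ <- if (mu != 0) sdev / mu else 0
  qcod <- if ((p75 + p25) != 0) (p75 - p25) / (p75 + p25) else 0
  energy <- sum(x^2)
  rms <- sqrt(mean(x^2))

  # ---- intensity histogram (23) on grey levels ----
  g <- disc$levels[disc$mask]
  ng <- disc$n_levels
  cnt <- tabulate(g, nbins = ng)
  p <- cnt / n
  gh_mu <- mean(g)
  gh_var <- mean((g - gh_mu)^2)
  gh_sd <- sqrt(gh_var)
  gh_skew <- if (gh_sd > 0) mean((g - gh_mu)^3) / gh_sd^3 else 0
  gh_kurt <- if (gh_sd > 0) mean((g - gh_mu)^4) / gh_sd^4 - 3 else 0
  gh_med <- median(g)
  gq <- quantile(g, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  gh_mode <- which.max(cnt)                    # ties: lowest level
  gh_iqr <- gq[3] - gq[2]
  gh_rng <- max(g) - min(g)
  gh_mad <- mean(abs(g - gh_mu))
  ginb <- g[g >= gq[1] & g <= gq[4]]
  gh_rmad <- if (length(ginb)) mean(abs(ginb - mean(ginb))) else 0
  gh_medad <- mean(abs(g - gh_med))
  gh_cov <- if (gh_mu != 0) gh_sd / gh_mu else 0
  gh_qcod <- if ((gq[3] + gq[2]) != 0) (gq[3] - gq[2]) / (gq[3] + gq[2]) else 0
  pp <- p[p > 0]
  gh_entropy <- -sum(pp * log2(pp))
  gh_uniformity <- sum(p^2)
  # histogram gradient over the level axis (central differences)
  grad <- if (ng >= 2) {
    gd <- numeric(ng)
    gd[1] <- cnt[2] - cnt[1]
    gd[ng] <- cnt[ng] - cnt[ng - 1]
    if (ng > 2) gd[2:(ng - 1)] <- (cnt[3:ng] - cnt[1:(ng - 2)]) / 2
    gd
  } else 0
  gh_maxgrad <- max(grad)
  gh_maxgrad_lv <- which.max(grad)
  gh_mingrad <- min(grad)
  gh_mingrad_lv <- which.min(grad)

  # ---- intensity-volume histogram (7) ----
  ivh <- ivh_features(x)

  tibble(
    int_local_intensity_peak = local_peak,
    int_global_intensity_peak = global_peak,
    int_stat_mean = mu, int_stat_variance = vr, int_stat_skewness = skew,
    int_stat_kurtosis = kurt, int_stat_median = med, int_stat_minimum = min(x),
    int_stat_p10 = p10, int_stat_p90 = p90, int_stat_maximum = maxv,
    int_stat_iqr = iqr, int_stat_range = rng, int_stat_mad = mad_mean,
    int_stat_rmad = rmad, int_stat_medad = medad, int_stat_cov = cov_,
    int_stat_qcod = qcod, int_stat_energy = energy, int_stat_rms = rms,
    int_hist_mean = gh_mu, int_hist_variance = gh_var, int_hist_skewness = gh_skew,
    int_hist_kurtosis = gh_kurt, int_hist_median = gh_med, int_hist_minimum = min(g),
    int_hist_p10 = gq[1], int_hist_p90 = gq[4], int_hist_maximum = max(g),
    int_hist_mode = gh_mode, int_hist_iqr = gh_iqr, int_hist_range = gh_rng,
    int_hist_mad = gh_mad, int_hist_rmad = gh_rmad, int_hist_medad = gh_medad,
    int_hist_cov = gh_cov, int_hist_qcod = gh_qcod, int_hist_entropy = gh_entropy,
    int_hist_uniformity = gh_uniformity,
    int_hist_max_gradient = gh_maxgrad, int_hist_max_gradient_level = gh_maxgrad_lv,
    int_hist_min_gradient = gh_mingrad, int_hist_min_gradient_level = gh_mingrad_lv,
    int_ivh_v10 = unname(ivh["v10"]), int_ivh_v90 = unname(ivh["v90"]),
    int_ivh_i10 = unname(ivh["i10"]), int_ivh_i90 = unname(ivh["i90"]),
    int_ivh_v10_minus_v90 = unname(ivh["v10"] - ivh["v90"]),
    int_ivh_i10_minus_i90 = unname(ivh["i10"] - ivh["i90"]),
    int_ivh_auc = unname(ivh["auc"])
  )
}

# Intensity-volume histogram on continuous SUVs. Intensity fractions are
# relative to the in-mask [min, max] range; V(g) is the fraction of voxels
# whose intensity fraction is at least g; I(v) is the smallest intensity
# such that at most fraction v of the volume is at or above it. Constant
# regions pin V = 1 everywhere and I10 = I90 = the constant.
ivh_features <- function(x) {
  mn <- min(x); mx <- max(x)
  if (mx == mn) {
    return(c(v10 = 1, v90 = 1, i10 = mn, i90 = mn, auc = 1))
  }
  n <- length(x)
  xs <- sort(x)
  gs <- (xs - mn) / (mx - mn)
  # V(g) = fraction of voxels with intensity fraction >= g, via one ranked pass
  vol_at_frac <- function(gfrac) (n - findInterval(gfrac, gs, left.open = TRUE)) / n
  int_at_vol <- function(v) {
    xu <- unique(xs)
    above <- (n - findInterval(xu, xs, left.open = TRUE)) / n   # mean(x >= t)
    ok <- which(above <= v)
    if (!length(ok)) mx else xu[ok[1]]
  }
  gg <- seq(0, 1, length.out = 1000)
  vv <- vol_at_frac(gg)
  auc <- sum((vv[-1] + vv[-length(vv)]) / 2) * (gg[2] - gg[1])
  c(v10 = vol_at_frac(0.10), v90 = vol_at_frac(0.90),
    i10 = int_at_vol(0.10), i90 = int_at_vol(0.90), auc = auc)
}
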