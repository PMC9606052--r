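#' Pairwise lesion centroid distances
#'
#' Euclidean distances between lesion centroids (volume-weighted, i.e. the
#' mean of voxel center positions) in physical mm.
#'
#' @param lesions A `lesion_set` with at least one lesion.
#' @return A symmetric matrix with zero diagonal, one row/column per lesion.
#' @export
centroid_distances <- function(lesions) {
  stopifnot(inherits(lesions, "lesion_set"))
  sm <- lesions$lesions
  if (nrow(sm) < 1) abort("lesion set is empty")
  cen <- as.matrix(sm[, c("centroid_x_mm", "centroid_y_mm", "centroid_z_mm")])
  m <- as.matrix(stats::dist(cen))
  dimnames(m) <- list(sm$lesion, sm$lesion)
  m
}

#' Patient-level dissemination features
#'
#' The 18-feature dissemination panel: lesion count; four distance features
#' (Dmax and Dmean from the bulk -- largest -- lesion, and over all lesion
#' pairs); five spread statistics (range, SD, coefficient of variation,
#' max/min ratio, IQR) for each of per-lesion SUVpeak and SUVmean; and three
#' volume-spread features (range, SD, and the bulk volume fraction = largest
#' lesion volume / MTV). Single-lesion patients take pinned degenerate
#' values: distances and spreads 0, ratios and bulk fraction 1.
#'
#' @param lesions A `lesion_set` with populated summaries.
#' @return A one-row tibble with 18 `diss_*` columns.
#' @export
dissemination_features <- function(lesions) {
  stopifnot(inherits(lesions, "lesion_set"))
  sm <- lesions$lesions
  n <- nrow(sm)
  if (n < 1) abort("lesion set is empty")
  if (any(sm$volume_ml <= 0)) abort("zero-volume lesion")
  spread <- function(v) {
    if (n == 1L) {
      c(range = 0, sd = 0, cov = 0, ratio = 1, iqr = 0)
    } else {
      mu <- mean(v)
      c(range = max(v) - min(v), sd = sd(v),
        cov = if (mu != 0) sd(v) / mu else 0,
        ratio = max(v) / min(v),
        iqr = unname(quantile(v, 0.75) - quantile(v, 0.25)))
    }
  }
  bulk <- which.max(sm$volume_ml)   # summaries are volume-ordered: bulk == 1
  if (n == 1L) {
    dmax_bulk <- dmax_pat <- dmean_bulk <- dmean_pat <- 0
  } else {
    dm <- centroid_distances(lesions)
    dmax_bulk <- max(dm[bulk, ])
    dmean_bulk <- mean(dm[bulk, -bulk])
    dmax_pat <- max(dm)
    dmean_pat <- mean(dm[upper.tri(dm)])
  }
  sp_pk <- spread(sm$suv_peak)
  sp_mn <- spread(sm$suv_mean)
  mtv <- sum(sm$volume_ml)
  tibble(
    diss_n_lesions = n,
    diss_dmax_bulk = dmax_bulk,
    diss_dmax_patient = dmax_pat,
    diss_dmean_bulk = dmean_bulk,
    diss_dmean_patient = dmean_pat,
    diss_suv_peak_range = unname(sp_pk["range"]), diss_suv_peak_sd = unname(sp_pk["sd"]),
    diss_suv_peak_cov = unname(sp_pk["cov"]),
    diss_suv_peak_max_min_ratio = unname(sp_pk["ratio"]),
    diss_suv_peak_iqr = unname(sp_pk["iqr"]),
    diss_suv_mean_range = unname(sp_mn["range"]), diss_suv_mean_sd = unname(sp_mn["sd"]),
    diss_suv_mean_cov = unname(sp_mn["cov"]),
    diss_suv_mean_max_min_ratio = unname(sp_mn["ratio"]),
    diss_suv_mean_iqr = unname(sp_mn["iqr"]),
    diss_volume_range = if (n == 1L) 0 else max(sm$volume_ml) - min(sm$volume_ml),
    diss_volume_sd = if (n == 1L) 0 else sd(sm$volume_ml),
    diss_bulk_fraction = sm$volume_ml[bulk] / mtv
  )
}
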