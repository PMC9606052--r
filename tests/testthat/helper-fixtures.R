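# fixtures built in code; no files on disk

# hard-edged ball image (no rim, no noise) for clean volume arithmetic
ball_image <- function(n = 31, spacing = c(1, 1, 1), r_mm = 10, suv = 8,
                       background = 1, center = NULL) {
  if (is.null(center)) center <- (n + 1) / 2 * spacing
  g <- as.matrix(expand.grid(i = 1:n, j = 1:n, k = 1:n))
  pos <- sweep(g - 1, 2, spacing, "*")
  d2 <- rowSums(sweep(pos, 2, center)^2)
  a <- array(background, c(n, n, n))
  a[d2 <= r_mm^2] <- suv
  suv_image(a, spacing = spacing)
}

# add a second ball to an existing image
add_ball <- function(image, center_mm, r_mm, suv) {
  d <- dim(image$data)
  g <- as.matrix(expand.grid(i = 1:d[1], j = 1:d[2], k = 1:d[3]))
  pos <- sweep(sweep(g - 1, 2, image$spacing, "*"), 2, image$origin, "+")
  d2 <- rowSums(sweep(pos, 2, center_mm)^2)
  image$data[d2 <= r_mm^2] <- suv
  image
}

# construct a resampled_volume directly (already-on-grid data)
as_resampled <- function(data, mask, spacing = c(2, 2, 2)) {
  structure(list(data = data, mask = mask, spacing = spacing,
                 provenance = list(original_spacing = spacing,
                                   original_dim = dim(data),
                                   interpolation = "native",
                                   mask_threshold = 0.5)),
            class = "resampled_volume")
}

# random discretized volume for texture tests: dims d, n gray levels,
# voxel inclusion probability p_mask
random_disc <- function(d, n_levels = 4, p_mask = 0.85, seed = 1) {
  set.seed(seed)
  mask <- array(runif(prod(d)) < p_mask, d)
  if (!any(mask)) mask[1] <- TRUE
  lv <- array(NA_integer_, d)
  lv[mask] <- sample.int(n_levels, sum(mask), replace = TRUE)
  structure(list(levels = lv, mask = mask, n_levels = n_levels,
                 bin_width = 0.25, anchor = 0, spacing = c(2, 2, 2)),
            class = "discretized_volume")
}

disc_from_levels <- function(lv) {
  structure(list(levels = lv, mask = !is.na(lv),
                 n_levels = max(lv, na.rm = TRUE),
                 bin_width = 0.25, anchor = 0, spacing = c(2, 2, 2)),
            class = "discretized_volume")
}

# small, fast phantom / cohort settings used across modeling tests
small_phantom <- function(...) {
  phantom_config(grid_shape = c(40, 40, 40), spacing = c(2, 2, 2),
                 n_lesions_range = c(1, 4), lesion_radius_range_mm = c(5, 10),
                 lesion_suv_range = c(5, 16), ...)
}

# shared expensive fixture: one fully-extracted synthetic cohort (n = 150),
# memoised across test files within a session
.petrad_test_cache <- new.env(parent = emptyenv())

cached_cohort_features <- function() {
  if (is.null(.petrad_test_cache$feats)) {
    ph <- small_phantom()
    co <- cohort_config(n_patients = 150, seed = 42)
    coh <- generate_cohort(co, ph)
    .petrad_test_cache$cohort <- coh
    .petrad_test_cache$feats <- extract_cohort_features(coh)
  }
  .petrad_test_cache$feats
}

cached_cohort <- function() {
  invisible(cached_cohort_features())
  .petrad_test_cache$cohort
}
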