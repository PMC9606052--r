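# lesion dissemination features

# minimal lesion_set from a summary table (geometry-only tests)
fake_lesion_set <- function(volumes, centers, suv_peak = NULL, suv_mean = NULL,
                            suv_max = NULL) {
  n <- length(volumes)
  ord <- order(-volumes)
  sm <- tibble::tibble(
    lesion = seq_len(n),
    n_voxels = as.integer(volumes[ord] * 125),
    volume_ml = volumes[ord],
    centroid_x_mm = centers[ord, 1], centroid_y_mm = centers[ord, 2],
    centroid_z_mm = centers[ord, 3],
    suv_max = (suv_max %||% rep(8, n))[ord],
    suv_mean = (suv_mean %||% rep(6, n))[ord],
    suv_peak = (suv_peak %||% rep(7, n))[ord]
  )
  structure(list(label_map = NULL, spacing = c(2, 2, 2), origin = c(0, 0, 0),
                 lesions = sm), class = "lesion_set")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("centroid distances follow the 3-4-5 triangle", {
  ls <- fake_lesion_set(c(10, 5), rbind(c(0, 0, 0), c(30, 40, 0)))
  m <- centroid_distances(ls)
  expect_equal(m[1, 2], 50)
  expect_equal(m[2, 1], 50)
  expect_equal(diag(m), c(0, 0), ignore_attr = TRUE)
  # single lesion: 1 x 1 zero matrix
  m1 <- centroid_distances(fake_lesion_set(3, rbind(c(5, 5, 5))))
  expect_equal(dim(m1), c(1, 1))
  expect_equal(m1[1, 1], 0)
})

test_that("the colinear three-lesion worked example is exact", {
  ls <- fake_lesion_set(c(10, 5, 5),
                        rbind(c(0, 0, 0), c(100, 0, 0), c(200, 0, 0)))
  d <- dissemination_features(ls)
  expect_equal(ncol(d), 18)
  expect_equal(d$diss_n_lesions, 3)
  expect_equal(d$diss_dmax_bulk, 200)
  expect_equal(d$diss_dmax_patient, 200)
  expect_equal(d$diss_dmean_bulk, 150)
  expect_equal(d$diss_bulk_fraction, 0.5)
})

test_that("single-lesion patients take the pinned degenerate values", {
  ls <- fake_lesion_set(7, rbind(c(10, 20, 30)))
  d <- dissemination_features(ls)
  expect_equal(d$diss_dmax_bulk, 0)
  expect_equal(d$diss_dmax_patient, 0)
  expect_equal(d$diss_suv_peak_sd, 0)
  expect_equal(d$diss_suv_peak_max_min_ratio, 1)
  expect_equal(d$diss_suv_mean_iqr, 0)
  expect_equal(d$diss_volume_range, 0)
  expect_equal(d$diss_bulk_fraction, 1)
})

test_that("dissemination features are rigid-motion invariant", {
  set.seed(21)
  n <- 5
  cen <- matrix(runif(n * 3, 0, 100), n, 3)
  vols <- runif(n, 2, 30)
  pk <- runif(n, 5, 20); mn <- runif(n, 4, 10)
  ls1 <- fake_lesion_set(vols, cen, suv_peak = pk, suv_mean = mn)
  # random rotation + translation
  th <- 0.83
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  R2 <- rbind(c(1, 0, 0), c(0, cos(0.3), -sin(0.3)), c(0, sin(0.3), cos(0.3)))
  cen2 <- t(R2 %*% R %*% t(cen)) + matrix(c(12, -5, 40), n, 3, byrow = TRUE)
  ls2 <- fake_lesion_set(vols, cen2, suv_peak = pk, suv_mean = mn)
  d1 <- dissemination_features(ls1)
  d2 <- dissemination_features(ls2)
  expect_equal(as.numeric(d1), as.numeric(d2), tolerance = 1e-9)
})

test_that("Dmax_patient >= Dmax_bulk and label-permutation invariance", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(2:6, 1)
    cen <- matrix(runif(n * 3, 0, 200), n, 3)
    vols <- runif(n, 1, 50)
    ls <- fake_lesion_set(vols, cen)
    d <- dissemination_features(ls)
    expect_gte(d$diss_dmax_patient, d$diss_dmax_bulk)
    expect_gt(d$diss_bulk_fraction, 0)
    expect_lte(d$diss_bulk_fraction, 1)
    # permuting input order changes nothing (construction sorts by volume)
    p <- sample(n)
    d2 <- dissemination_features(fake_lesion_set(vols[p], cen[p, , drop = FALSE]))
    expect_equal(d$diss_volume_sd, d2$diss_volume_sd)
    expect_equal(d$diss_dmax_patient, d2$diss_dmax_patient)
  }
})

test_that("dissemination from a real delineation is consistent with geometry", {
  img <- ball_image(n = 40, spacing = c(2, 2, 2), r_mm = 10, suv = 8,
                    center = c(20, 20, 20))
  img <- add_ball(img, c(60, 20, 20), 9.8, 12)
  ls <- delineate(img)
  d <- dissemination_features(ls)
  expect_equal(d$diss_n_lesions, 2)
  expect_equal(d$diss_dmax_bulk, 40, tolerance = 0.05)
  expect_equal(d$diss_dmax_bulk, d$diss_dmax_patient)
})
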