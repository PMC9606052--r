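# synthetic phantom and cohort generator

test_that("rendered sphere support matches analytic volume", {
  img <- suv_image(array(0, c(16, 16, 16)), spacing = c(2, 2, 2))
  r <- 6.2
  out <- render_lesion(img, center_mm = c(16, 16, 16), radius_mm = r, peak_suv = 10)
  core <- sum(out$data >= 10 - 1e-9) * prod(img$spacing)
  expect_lt(abs(core - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3), 0.02)
})

test_that("rendering a lesion at background intensity changes nothing beyond noise", {
  set.seed(5)
  img <- suv_image(array(pmax(rnorm(20^3, 1, 0.1), 0), c(20, 20, 20)),
                   spacing = c(2, 2, 2))
  out <- render_lesion(img, c(19, 19, 19), radius_mm = 8, peak_suv = 1)
  dif <- abs(out$data - img$data)
  expect_lt(max(dif), 6 * 0.1)          # bounded by noise excursions
  expect_lt(mean(dif), 0.1)
})

test_that("two disjoint spheres add their voxel counts", {
  img <- suv_image(array(0, c(32, 32, 16)), spacing = c(2, 2, 2))
  a <- render_lesion(img, c(12, 12, 15), 6, 10)
  na <- sum(a$data > 5)
  b <- render_lesion(img, c(48, 48, 15), 7, 10)
  nb <- sum(b$data > 5)
  both <- render_lesion(a, c(48, 48, 15), 7, 10)
  expect_equal(sum(both$data > 5), na + nb)
})

test_that("a lesion whose core leaves the grid errors with its center", {
  img <- suv_image(array(0, c(16, 16, 16)), spacing = c(2, 2, 2))
  expect_error(render_lesion(img, c(2, 15, 15), 8, 10), "2\\.0, 15\\.0, 15\\.0")
})

test_that("generate_patient honors the lesion-count range and is deterministic", {
  cfg <- phantom_config(grid_shape = c(40, 40, 40), spacing = c(2, 2, 2),
                        n_lesions_range = c(3, 3),
                        lesion_radius_range_mm = c(5, 8),
                        lesion_suv_range = c(8, 20))
  p1 <- generate_patient(cfg, seed = 11)
  expect_equal(nrow(p1$truth), 3)
  p2 <- generate_patient(cfg, seed = 11)
  expect_identical(p1$image$data, p2$image$data)
  expect_identical(p1$truth, p2$truth)
  # peaks at least 8: brightest voxel reaches the smallest peak
  expect_gte(max(p1$image$data), 8 - 1e-6)
})

test_that("rendered MTV is within 5% of the analytic super-threshold volume", {
  cfg <- phantom_config(grid_shape = c(40, 40, 40), spacing = c(2, 2, 2),
                        n_lesions_range = c(1, 2),
                        lesion_radius_range_mm = c(6.5, 12),
                        lesion_suv_range = c(6, 25))
  sigma <- mean(cfg$spacing)
  for (seed in 1:20) {
    p <- generate_patient(cfg, seed = seed)
    thr_vox <- sum(p$image$data >= cfg$mtv_suv_threshold)
    mtv <- thr_vox * prod(cfg$spacing) / 1000
    r_eff <- p$truth$radius_mm +
      sigma * sqrt(2 * pmax(log(p$truth$peak_suv / cfg$mtv_suv_threshold), 0))
    analytic <- sum(4 / 3 * pi * r_eff^3) / 1000
    expect_lt(abs(mtv - analytic) / analytic, 0.05)
  }
})

test_that("cohort prevalence is calibrated to the target", {
  ph <- phantom_config(grid_shape = c(36, 36, 36), spacing = c(3, 3, 3),
                       n_lesions_range = c(1, 2),
                       lesion_radius_range_mm = c(5, 8),
                       lesion_suv_range = c(5, 15))
  target <- 52 / 296
  prev <- vapply(1:15, function(s) {
    co <- cohort_config(n_patients = 100, prevalence_target = target, seed = s)
    mean(suppressWarnings(generate_cohort(co, ph))$outcome)
  }, numeric(1))
  expect_lt(abs(mean(prev) - target), 0.02)
})

test_that("null link coefficients give outcomes independent of features", {
  ph <- small_phantom()
  co <- cohort_config(n_patients = 400, outcome_link_coefficients = c(0, 0, 0),
                      seed = 2)
  feats <- petrad:::pilot_sample_features(ph, 10000, seed = 1)
  cal <- petrad:::calibrate_link(co, ph)
  expect_equal(mean(plogis(cal$intercept)), co$prevalence_target, tolerance = 1e-6)
})

test_that("a positive log-MTV coefficient raises the event rate above the median MTV", {
  ph <- small_phantom()
  co <- cohort_config(n_patients = 10, outcome_link_coefficients = c(1, 0, 0),
                      seed = 3)
  cal <- petrad:::calibrate_link(co, ph)
  feats <- petrad:::pilot_sample_features(ph, 10000, seed = 77)
  z <- sweep(sweep(feats, 2, cal$mu), 2, cal$sd, "/")
  eta <- cal$intercept + z %*% co$outcome_link_coefficients
  set.seed(9)
  y <- rbinom(10000, 1, plogis(eta))
  hi <- feats[, "log_mtv"] > median(feats[, "log_mtv"])
  expect_gt(mean(y[hi]), mean(y[!hi]))
})

test_that("bayes_auc of a null link is 0.5 and of a strong link is high", {
  ph <- small_phantom()
  co0 <- cohort_config(outcome_link_coefficients = c(0, 0, 0), seed = 1)
  expect_equal(bayes_auc(co0, ph, n_draws = 2e4, seed = 1), 0.5, tolerance = 0.02)
  co1 <- cohort_config(outcome_link_coefficients = c(3, 3, 3), seed = 1)
  expect_gt(bayes_auc(co1, ph, n_draws = 2e4, seed = 1), 0.85)
})

test_that("invalid configs are rejected with informative messages", {
  expect_error(phantom_config(n_lesions_range = c(0, 5)), "n_lesions_range")
  expect_error(phantom_config(lesion_suv_range = c(3, 10)), "threshold")
  expect_error(phantom_config(spacing = c(2, -2, 2)), "spacing")
  expect_error(cohort_config(prevalence_target = 1.2), "prevalence_target")
})
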