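# experiment configuration and end-to-end driver

tiny_experiment_config <- function(out_dir = NULL, seed = 9,
                                   coefficients = c(log_mtv = 0.8, suv_peak = 0.3,
                                                    dmax_bulk = 0.5)) {
  experiment_config(
    phantom = phantom_config(grid_shape = c(36, 36, 36), spacing = c(2, 2, 2),
                             n_lesions_range = c(1, 3),
                             lesion_radius_range_mm = c(5, 9),
                             lesion_suv_range = c(5, 14)),
    cohort = cohort_config(n_patients = 40, outcome_link_coefficients = coefficients,
                           seed = 21),
    approaches = c("reference", "dissemination"),
    oversampling_options = c("none", "interpolate"),
    reduction_options = c("none", "anova_top10pct"),
    n_folds = 3, n_repeats = 2, num_trees = 100,
    seed = seed, out_dir = out_dir)
}

test_that("the default configuration validates and round-trips through YAML", {
  cfg <- tiny_experiment_config()
  expect_s3_class(cfg, "experiment_config")
  path <- tempfile(fileext = ".yaml")
  write_experiment_config(cfg, path)
  cfg2 <- validate_config(path)
  expect_equal(unclass(cfg2)[setdiff(names(cfg2), c("phantom", "cohort"))],
               unclass(cfg)[setdiff(names(cfg), c("phantom", "cohort"))])
  expect_equal(unclass(cfg2$phantom), unclass(cfg$phantom))
  expect_equal(unclass(cfg2$cohort), unclass(cfg$cohort))
})

test_that("invalid configurations report every violation at once", {
  cfg <- unclass(tiny_experiment_config())
  cfg$approaches <- c("reference", "bogus")
  cfg$min_volume_ml <- -3
  cfg$n_folds <- 1
  err <- tryCatch(validate_config(cfg), error = conditionMessage)
  expect_match(err, "bogus")
  expect_match(err, "valid ids")
  expect_match(err, "min_volume_ml")
  expect_match(err, "n_folds")
  expect_error(validate_config("/nonexistent/path.yaml"), "does not exist")
})

test_that("run_experiment produces the full grid and deterministic CSVs", {
  d1 <- file.path(tempdir(), "exp1"); d2 <- file.path(tempdir(), "exp2")
  cfg1 <- tiny_experiment_config(out_dir = d1)
  rep1 <- run_experiment(cfg1, verbose = FALSE)
  expect_equal(nrow(rep1$grid), 2 * 2 * 2)     # approaches x oversampling x reduction
  expect_equal(nrow(rep1$best), 2)
  expect_true(all(rep1$grid$mean_cv_auc >= 0 & rep1$grid$mean_cv_auc <= 1))
  expect_gte(rep1$concordance$concordance, 0)
  expect_true(is.finite(rep1$dmax_mtv_correlation))
  expect_named(rep1$importance, c("reference", "dissemination"))
  for (imp in rep1$importance) {
    expect_equal(sum(imp$importance$importance), 1, tolerance = 1e-9)
  }
  # byte-identical outputs on rerun with the same config + seed
  cfg2 <- tiny_experiment_config(out_dir = d2)
  rep2 <- run_experiment(cfg2, verbose = FALSE)
  for (f in c("grid.csv", "best_models.csv", "summary.csv", "importance.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("a null cohort yields near-chance best CV-AUCs", {
  cfg <- experiment_config(
    phantom = phantom_config(grid_shape = c(36, 36, 36), spacing = c(2, 2, 2),
                             n_lesions_range = c(1, 3),
                             lesion_radius_range_mm = c(5, 9),
                             lesion_suv_range = c(5, 14)),
    cohort = cohort_config(n_patients = 60, outcome_link_coefficients = c(0, 0, 0),
                           seed = 23),
    approaches = c("reference", "dissemination"),
    oversampling_options = c("none", "interpolate"),
    reduction_options = c("none", "anova_top10pct"),
    n_folds = 3, n_repeats = 5, num_trees = 100, seed = 31)
  rep_null <- run_experiment(cfg, verbose = FALSE)
  expect_true(all(rep_null$best$mean_cv_auc > 0.45 &
                  rep_null$best$mean_cv_auc < 0.60))
})
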