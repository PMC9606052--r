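# lesion selection, aggregation and feature-table assembly

test_that("largest and hottest selection follow volume and SUVmax", {
  sm <- tibble::tibble(lesion = 1:2, n_voxels = c(100L, 50L),
                       volume_ml = c(10, 5),
                       centroid_x_mm = c(0, 10), centroid_y_mm = 0, centroid_z_mm = 0,
                       suv_max = c(12, 18), suv_mean = c(6, 9), suv_peak = c(10, 15))
  ls <- structure(list(lesions = sm), class = "lesion_set")
  expect_equal(select_largest(ls), 1)
  expect_equal(select_hottest(ls), 2)
  one <- structure(list(lesions = sm[1, ]), class = "lesion_set")
  expect_equal(select_largest(one), select_hottest(one))
  empty <- structure(list(lesions = sm[0, ]), class = "lesion_set")
  expect_error(select_largest(empty), "empty")
})

test_that("aggregation takes elementwise maximum or median", {
  tbl <- tibble::tibble(f1 = c(2, 5, 3), f2 = c(1, 1, 7))
  expect_equal(aggregate_lesions(tbl, "maximum")$f1, 5)
  expect_equal(aggregate_lesions(tbl, "median")$f1, 3)
  expect_equal(aggregate_lesions(tbl, "median")$f2, 1)
  expect_equal(as.numeric(aggregate_lesions(tbl[2, ], "maximum")), c(5, 1))
})

test_that("feature tables honor the per-approach column contracts", {
  feats <- cached_cohort_features()
  expected <- c(reference = 3, largest = 485, hottest = 485, patient_mtv = 485,
                maximum = 485, median = 485, dissemination = 23,
                diss_patient_mtv = 503, diss_largest = 503, diss_hottest = 503,
                diss_maximum = 503, diss_median = 503)
  for (ap in names(expected)) {
    tbl <- build_feature_table(feats, ap)
    expect_equal(ncol(tbl) - 2L, unname(expected[ap]))
    expect_false(anyNA(tbl))
    expect_setequal(unique(feats$patients$patient_id), tbl$patient_id)
  }
  ref <- build_feature_table(feats, "reference")
  expect_setequal(setdiff(names(ref), c("patient_id", "outcome")),
                  c("conv_mtv_ml", "conv_suv_peak", "diss_dmax_bulk"))
  # diss_* tables carry 498 radiomics + 5 conventional columns
  dl <- build_feature_table(feats, "diss_largest")
  rad <- sum(startsWith(names(dl), "morph_") | startsWith(names(dl), "int_") |
             startsWith(names(dl), "tex_") | startsWith(names(dl), "diss_"))
  expect_equal(rad, 498)
  expect_equal(sum(startsWith(names(dl), "conv_")), 5)
})

test_that("tables agree across approaches for single-lesion patients", {
  feats <- cached_cohort_features()
  singles <- feats$lesion_summaries %>%
    dplyr::count(patient_id) %>% dplyr::filter(n == 1) %>% dplyr::pull(patient_id)
  expect_gt(length(singles), 3)
  tabs <- lapply(c("largest", "hottest", "maximum", "median"),
                 function(ap) build_feature_table(feats, ap))
  for (t2 in tabs[-1]) {
    expect_equal(as.data.frame(tabs[[1]][tabs[[1]]$patient_id %in% singles, ]),
                 as.data.frame(t2[t2$patient_id %in% singles, ]),
                 tolerance = 1e-12)
  }
})

test_that("identical inputs give identical tables", {
  feats <- cached_cohort_features()
  t1 <- build_feature_table(feats, "diss_median")
  t2 <- build_feature_table(feats, "diss_median")
  expect_identical(t1, t2)
})

test_that("concordance counts largest==hottest patients", {
  mk <- function(vols, maxes, pid) {
    tibble::tibble(patient_id = pid, lesion = seq_along(vols),
                   n_voxels = 10L, volume_ml = vols,
                   centroid_x_mm = 0, centroid_y_mm = 0, centroid_z_mm = 0,
                   suv_max = maxes, suv_mean = 5, suv_peak = maxes - 1)
  }
  # patient 1: concordant; patient 2: discordant (small largest lesion)
  feats <- structure(list(
    lesion_summaries = dplyr::bind_rows(mk(c(20, 5), c(15, 8), 1),
                                        mk(c(6, 5), c(9, 14), 2)),
    patients = tibble::tibble(patient_id = 1:2, outcome = c(0, 1))
  ), class = "cohort_features")
  cc <- lesion_concordance(feats)
  expect_equal(cc$concordance, 0.5)
  expect_equal(cc$n_mismatch, 1)
  expect_equal(sum(cc$breakdown$n), 1)
  expect_equal(cc$breakdown$n[cc$breakdown$category == "largest_volume_lt_10ml"], 1)
})

test_that("concordance on random lesion sets matches a direct count", {
  set.seed(31)
  rows <- list()
  match_direct <- logical(300)
  for (i in 1:300) {
    n <- sample(1:5, 1)
    vols <- runif(n, 1, 60)
    maxes <- runif(n, 4.5, 30)   # intensity independent of size
    rows[[i]] <- tibble::tibble(patient_id = i, lesion = seq_len(n),
                                n_voxels = 10L, volume_ml = vols,
                                centroid_x_mm = 0, centroid_y_mm = 0,
                                centroid_z_mm = 0, suv_max = maxes,
                                suv_mean = 5, suv_peak = maxes)
    match_direct[i] <- which.max(vols) == which.max(maxes)
  }
  feats <- structure(list(lesion_summaries = dplyr::bind_rows(rows),
                          patients = tibble::tibble(patient_id = 1:300, outcome = 0)),
                     class = "cohort_features")
  cc <- lesion_concordance(feats)
  expect_equal(cc$concordance, mean(match_direct))
})
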