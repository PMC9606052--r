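# threshold delineation, mask editing, QC

test_that("delineation applies the SUV and volume thresholds", {
  # one ~5 mL blob at SUV 8 on a SUV-1 background
  img <- ball_image(n = 24, spacing = c(2, 2, 2), r_mm = 10.6, suv = 8)
  ls <- delineate(img)
  expect_equal(nrow(ls$lesions), 1)
  expect_lt(abs(ls$lesions$volume_ml - 5), 5 * 0.06 + prod(img$spacing) / 1000)
  # ~2 mL blob: below the 3 mL cut-off
  img2 <- ball_image(n = 24, spacing = c(2, 2, 2), r_mm = 7.8, suv = 8)
  expect_equal(nrow(delineate(img2)$lesions), 0)
  # SUV 3.9: below the threshold everywhere
  img3 <- ball_image(n = 24, spacing = c(2, 2, 2), r_mm = 10.6, suv = 3.9)
  expect_equal(nrow(delineate(img3)$lesions), 0)
  # non-finite voxels are rejected
  img$data[1] <- NaN
  expect_error(delineate(img), "non-finite")
})

test_that("delineation matches a flood-fill component oracle on random grids", {
  for (seed in 1:30) {
    set.seed(seed)
    d <- c(sample(5:12, 1), sample(5:12, 1), sample(5:12, 1))
    a <- array(runif(prod(d)) * 8, d)
    img <- suv_image(a, spacing = c(2, 2, 2))
    ls <- delineate(img, suv_threshold = 4, min_volume_ml = 0)
    lv <- array(NA_integer_, d)
    lv[a >= 4] <- 1L
    oracle <- oracle_zone_label(lv, oracle_offs_26())
    # identical partitions: label images agree up to renaming
    if (max(oracle) == 0) {
      expect_equal(nrow(ls$lesions), 0)
    } else {
      expect_equal(sort(table(oracle[oracle > 0])), sort(table(ls$label_map[ls$label_map > 0])),
                   ignore_attr = TRUE)
      key <- paste(ls$label_map[ls$label_map > 0], oracle[oracle > 0])
      # bijection between label sets
      expect_equal(length(unique(key)), nrow(ls$lesions))
    }
  }
})

test_that("raising thresholds never increases the lesion count", {
  set.seed(99)
  a <- array(runif(16^3) * 10, c(16, 16, 16))
  img <- suv_image(a, spacing = c(2, 2, 2))
  n_thr <- vapply(c(3, 4, 5, 6, 7), function(t) nrow(delineate(img, t, 0)$lesions),
                  numeric(1))
  # counts can rise as components split, so check the volume-filtered chain
  n_vol <- vapply(c(0, 0.05, 0.2, 1, 3), function(v) nrow(delineate(img, 4, v)$lesions),
                  numeric(1))
  expect_true(all(diff(n_vol) <= 0))
  # and strict monotonicity of the selected voxel count with SUV threshold
  vox <- vapply(c(3, 4, 5, 6, 7), function(t) sum(delineate(img, t, 0)$label_map > 0),
                numeric(1))
  expect_true(all(diff(vox) <= 0))
})

test_that("labels are ordered by decreasing volume", {
  img <- ball_image(n = 32, spacing = c(2, 2, 2), r_mm = 8, suv = 8,
                    center = c(14, 14, 14))
  img <- add_ball(img, c(44, 44, 44), 12, 6)
  ls <- delineate(img)
  expect_equal(ls$lesions$volume_ml, sort(ls$lesions$volume_ml, decreasing = TRUE))
  expect_equal(ls$lesions$lesion, seq_len(nrow(ls$lesions)))
})

test_that("add_lesion recovers a sub-volume component and is idempotent", {
  img <- ball_image(n = 24, spacing = c(2, 2, 2), r_mm = 7.8, suv = 8)   # ~2 mL
  ls <- delineate(img)
  expect_equal(nrow(ls$lesions), 0)
  seedvox <- which(img$data >= 8, arr.ind = TRUE)[1, ]
  ls2 <- add_lesion(ls, img, seedvox)
  expect_equal(nrow(ls2$lesions), 1)
  expect_lt(abs(ls2$lesions$volume_ml - 2), 0.35)
  # seeding inside the existing lesion changes nothing
  ls3 <- add_lesion(ls2, img, seedvox)
  expect_identical(ls3$lesions, ls2$lesions)
  # background seed errors
  expect_error(add_lesion(ls2, img, c(1, 1, 1)), "below")
})

test_that("remove_region renumbers and round-trips", {
  img <- ball_image(n = 40, spacing = c(2, 2, 2), r_mm = 9, suv = 8,
                    center = c(16, 16, 16))
  img <- add_ball(img, c(56, 56, 56), 12, 7)
  img <- add_ball(img, c(56, 16, 40), 10, 9)
  ls <- delineate(img)
  expect_equal(nrow(ls$lesions), 3)
  ls2 <- remove_region(ls, 2)
  expect_equal(ls2$lesions$lesion, c(1, 2))
  expect_error(remove_region(ls2, 9), "no lesion")
  # remove then add back: summaries return
  removed_vox <- which(ls$label_map == 2, arr.ind = TRUE)[1, ]
  ls3 <- add_lesion(ls2, img, removed_vox)
  expect_equal(ls3$lesions, ls$lesions, tolerance = 1e-12)
  # remove all
  ls4 <- remove_region(remove_region(ls2, 1), 1)
  expect_equal(nrow(ls4$lesions), 0)
})

test_that("per-lesion summaries are recomputable from label map and image", {
  img <- ball_image(n = 24, spacing = c(2, 2, 2), r_mm = 9, suv = 8)
  ls <- delineate(img)
  re <- summarize_lesions(img, ls$label_map)
  expect_equal(as.data.frame(re), as.data.frame(ls$lesions), tolerance = 1e-12)
})

test_that("scan QC implements the hepatic/glucose/activity rule", {
  expect_equal(check_scan_quality(2.0, 5.0)$verdict, "pass")
  expect_equal(check_scan_quality(3.5, 5.0, 0.60)$verdict, "pass_by_activity")
  expect_equal(check_scan_quality(3.5, 5.0, 0.90)$verdict, "fail")
  expect_equal(check_scan_quality(2.0, 12.0)$verdict, "fail")
  expect_equal(check_scan_quality(1.3, 10.9)$verdict, "pass")   # closed hepatic bound
  expect_error(check_scan_quality(-1, 5), "finite")
  expect_match(check_scan_quality(0.9, 5, 0.9)$reason, "hepatic")
})

test_that("delineation recovers the true lesion count on clearly visible phantoms", {
  cfg <- phantom_config(grid_shape = c(56, 56, 56), spacing = c(2, 2, 2),
                        n_lesions_range = c(1, 3),
                        lesion_radius_range_mm = c(9.2, 12),   # >= 3 mL cores
                        lesion_suv_range = c(8, 20))
  hits <- vapply(1:100, function(s) {
    p <- generate_patient(cfg, seed = s)
    nrow(delineate(p$image)$lesions) == nrow(p$truth)
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})
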