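# texture matrices and features against brute-force enumeration oracles

test_that("GLCM matches the worked 2x2 slice example", {
  # slice with columns of 1s and 2s; direction across the columns
  lv <- array(NA_integer_, c(2, 2, 1))
  lv[, 1, 1] <- 1L; lv[, 2, 1] <- 2L
  C <- petrad:::glcm_counts(lv, c(0, 1, 0), 2L)
  P <- C / sum(C)
  expect_equal(P[1, 2], 0.5)
  expect_equal(P[2, 1], 0.5)
  expect_equal(P[1, 1], 0)
  f <- petrad:::glcm_eval(C)
  names(f) <- petrad:::glcm_feature_names()
  expect_equal(unname(f["joint_entropy"]), 1)   # one bit
})

test_that("all six families match brute-force oracles on random small grids", {
  dirs3 <- petrad:::offsets_3d_13()
  for (seed in 1:12) {
    d <- c(sample(3:6, 1), sample(3:6, 1), sample(3:6, 1))
    disc <- random_disc(d, n_levels = 4, p_mask = 0.8, seed = seed)
    lv <- disc$levels
    ng <- disc$n_levels
    # GLCM + GLRLM: every 3D direction
    for (dd in seq_len(nrow(dirs3))) {
      off <- dirs3[dd, ]
      expect_equal(petrad:::glcm_counts(lv, off, ng), oracle_glcm(lv, off, ng),
                   ignore_attr = TRUE)
      expect_equal(petrad:::glrlm_counts(lv, off, ng), oracle_glrlm(lv, off, ng),
                   ignore_attr = TRUE)
    }
    # GLSZM / GLDZM (3D, 26-connected zones)
    zones <- petrad:::glszm_zones(lv, dirs3)
    expect_equal(petrad:::glszm_counts(zones, ng),
                 oracle_glszm(lv, oracle_offs_26(), ng), ignore_attr = TRUE)
    dmap <- petrad:::distance_map_cityblock(!is.na(lv), in_plane = FALSE)
    expect_equal(petrad:::gldzm_counts(zones, dmap, ng),
                 oracle_gldzm(lv, oracle_offs_26(), ng), ignore_attr = TRUE)
    # NGTDM / NGLDM
    st <- petrad:::ngtdm_stats(lv, petrad:::offsets_26(), ng)
    or <- oracle_ngtdm(lv, oracle_offs_26(), ng)
    expect_equal(st$s, or$s, tolerance = 1e-12)
    expect_equal(st$n, or$n)
    expect_equal(petrad:::ngldm_counts(lv, petrad:::offsets_26(), ng),
                 oracle_ngldm(lv, oracle_offs_26(), ng), ignore_attr = TRUE)
  }
})

test_that("in-plane (2D) matrices match oracles slice by slice", {
  dirs2 <- petrad:::offsets_2d_4()
  for (seed in 13:17) {
    disc <- random_disc(c(5, 5, 3), n_levels = 4, p_mask = 0.8, seed = seed)
    for (z in 1:3) {
      sl <- disc$levels[, , z, drop = FALSE]
      sl <- array(sl, c(5, 5, 1))
      for (dd in seq_len(nrow(dirs2))) {
        off <- dirs2[dd, ]
        expect_equal(petrad:::glcm_counts(sl, off, 4L), oracle_glcm(sl, off, 4L),
                     ignore_attr = TRUE)
        expect_equal(petrad:::glrlm_counts(sl, off, 4L), oracle_glrlm(sl, off, 4L),
                     ignore_attr = TRUE)
      }
      zones <- petrad:::glszm_zones(sl, dirs2)
      expect_equal(petrad:::glszm_counts(zones, 4L),
                   oracle_glszm(sl, oracle_offs_8(), 4L), ignore_attr = TRUE)
      dmap <- petrad:::distance_map_cityblock(!is.na(sl), in_plane = TRUE)
      expect_equal(petrad:::gldzm_counts(zones, dmap, 4L),
                   oracle_gldzm(sl, oracle_offs_8(), 4L, in_plane = TRUE),
                   ignore_attr = TRUE)
    }
  }
})

test_that("normalized matrices sum to one", {
  disc <- random_disc(c(6, 6, 6), n_levels = 4, seed = 99)
  lv <- disc$levels
  C <- petrad:::glcm_counts(lv, c(1, 0, 0), 4L)
  expect_equal(sum(C / sum(C)), 1, tolerance = 1e-9)
  R <- petrad:::glrlm_counts(lv, c(0, 1, 0), 4L)
  expect_equal(sum(R / sum(R)), 1, tolerance = 1e-9)
  zones <- petrad:::glszm_zones(lv, petrad:::offsets_3d_13())
  S <- petrad:::glszm_counts(zones, 4L)
  expect_equal(sum(S / sum(S)), 1, tolerance = 1e-9)
})

test_that("constant regions take their analytic degenerate values", {
  lv <- array(5L, c(4, 4, 4))
  disc <- disc_from_levels(lv)
  tf <- texture_features(disc)
  # single level: no co-occurrence contrast, run-length matrix concentrated
  expect_equal(tf$tex_glcm_contrast_3d_mrg, 0)
  expect_equal(tf$tex_glcm_joint_entropy_3d_mrg, 0)
  # single level: all runs share one grey level, so the grey-level
  # non-uniformity (normalized) is exactly 1
  expect_equal(tf$tex_glrlm_glnu_norm_3d_mrg, 1)
  expect_false(anyNA(tf))
  expect_true(all(vapply(tf, is.finite, logical(1))))
})

test_that("texture features are invariant to 90-degree rotations (merged 3D)", {
  disc <- random_disc(c(5, 6, 4), n_levels = 5, p_mask = 0.9, seed = 7)
  rot <- disc
  rot$levels <- aperm(disc$levels[, , dim(disc$levels)[3]:1, drop = FALSE], c(2, 1, 3))
  rot$mask <- !is.na(rot$levels)
  f1 <- texture_features(disc)
  f2 <- texture_features(rot)
  m3 <- grepl("_3d_mrg$", names(f1))
  expect_equal(as.numeric(f1[, m3]), as.numeric(f2[, m3]), tolerance = 1e-9)
})

test_that("texture never yields NaN on random tiny masks, including 1-voxel", {
  for (seed in 1:40) {
    d <- c(sample(1:4, 1), sample(1:4, 1), sample(1:4, 1))
    nl <- sample(c(1, 2, 5), 1)
    disc <- random_disc(d, n_levels = nl, p_mask = 0.7, seed = 1000 + seed)
    tf <- texture_features(disc)
    expect_equal(ncol(tf), 408)
    expect_false(anyNA(tf))
    expect_true(all(vapply(tf, is.finite, logical(1))))
  }
  # explicit 1-voxel region
  lv <- array(NA_integer_, c(3, 3, 3)); lv[2, 2, 2] <- 7L
  tf <- texture_features(disc_from_levels(lv))
  expect_false(anyNA(tf))
})
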