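#' Phantom configuration for synthetic multi-lesion SUV images
#'
#' Defines the study conditions the synthetic cohort emulates: a whole-body
#' sized SUV grid with soft-tissue background, and between 1 and 20
#' FDG-avid lesions per patient spanning roughly 1-500 mL with peak SUV up to
#' 40. Lesions are rendered as a uniform core at `peak_suv` with a 1-voxel
#' Gaussian edge (a partial-volume caricature) so that intensity and texture
#' features are non-degenerate.
#'
#' @param grid_shape Grid size in voxels (3 integers).
#' @param spacing Voxel spacing in mm (3 positive numbers).
#' @param background_suv Mean background SUV.
#' @param background_noise_sd SD of Gaussian background noise (truncated at 0).
#' @param n_lesions_range Inclusive integer range for the lesion count.
#' @param lesion_radius_range_mm Radius range (mm); the defaults correspond to
#'   sphere volumes of 1 to 500 mL. Radii are drawn log-uniformly, giving the
#'   right-skewed volume distribution typical of lymphoma lesions.
#' @param lesion_suv_range Peak SUV range; drawn log-uniformly. The lower end
#'   must exceed the delineation threshold (4.0) so every rendered lesion is
#'   detectable.
#' @param lesion_shape One of `"sphere"`, `"ellipsoid"`, `"blob"`.
#' @param mtv_suv_threshold SUV level used to record each lesion's true
#'   metabolic volume (the rendered volume at or above this level, i.e. core
#'   plus part of the smoothed rim); matches the delineation default.
#' @param seed Default seed used by [generate_patient()] when none is given.
#' @return A validated `phantom_config` list.
#' @export
phantom_config <- function(grid_shape = c(128, 128, 200),
                           spacing = c(2, 2, 2),
                           background_suv = 1.0,
                           background_noise_sd = 0.1,
                           n_lesions_range = c(1, 20),
                           lesion_radius_range_mm = c(6.2, 49.2),
                           lesion_suv_range = c(4.5, 40),
                           lesion_shape = c("sphere", "ellipsoid", "blob"),
                           mtv_suv_threshold = 4.0,
                           seed = 1L) {
  lesion_shape <- match.arg(lesion_shape)
  cfg <- list(grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
              background_suv = background_suv, background_noise_sd = background_noise_sd,
              n_lesions_range = as.integer(n_lesions_range),
              lesion_radius_range_mm = as.numeric(lesion_radius_range_mm),
              lesion_suv_range = as.numeric(lesion_suv_range),
              lesion_shape = lesion_shape,
              mtv_suv_threshold = mtv_suv_threshold, seed = as.integer(seed))
  errs <- character()
  if (length(cfg$grid_shape) != 3 || any(cfg$grid_shape < 8))
    errs <- c(errs, "grid_shape must be 3 integers >= 8")
  if (length(cfg$spacing) != 3 || any(cfg$spacing <= 0))
    errs <- c(errs, "spacing must be 3 positive numbers")
  if (cfg$background_noise_sd < 0) errs <- c(errs, "background_noise_sd must be >= 0")
  if (cfg$n_lesions_range[1] < 1 || cfg$n_lesions_range[2] < cfg$n_lesions_range[1])
    errs <- c(errs, "n_lesions_range must be an increasing range with min >= 1")
  if (cfg$lesion_radius_range_mm[1] <= 0 ||
      cfg$lesion_radius_range_mm[2] < cfg$lesion_radius_range_mm[1])
    errs <- c(errs, "lesion_radius_range_mm must be an increasing positive range")
  if (cfg$mtv_suv_threshold <= 0)
    errs <- c(errs, "mtv_suv_threshold must be positive")
  if (cfg$lesion_suv_range[1] <= cfg$mtv_suv_threshold)
    errs <- c(errs, "lesion_suv_range minimum must exceed the SUV delineation threshold")
  if (cfg$lesion_suv_range[2] < cfg$lesion_suv_range[1])
    errs <- c(errs, "lesion_suv_range must be increasing")
  if (length(errs)) abort(paste(c("invalid phantom_config:", errs), collapse = "\n  "))
  structure(cfg, class = "phantom_config")
}

#' Cohort configuration: outcome model for synthetic patients
#'
#' The binary endpoint (progression within 2 years) is drawn from a logistic
#' link on three standardized patient summaries: log metabolic tumor volume,
#' peak SUV, and the maximum distance from the largest (bulk) lesion to any
#' other lesion (Dmax_bulk). The intercept is calibrated by root-finding on a
#' 10,000-draw pilot simulation so that the expected prevalence matches
#' `prevalence_target` (default 52/296, the imbalance observed in the
#' motivating DLBCL cohort).
#'
#' @param n_patients Number of patients.
#' @param prevalence_target Target event fraction in (0, 1).
#' @param outcome_link_coefficients Named weights on standardized
#'   `(log_mtv, suv_peak, dmax_bulk)`.
#' @param link_intercept Optional fixed intercept; when `NULL` it is
#'   calibrated to the prevalence target.
#' @param endpoint_mode `"progression"` or `"pfs"`; label recorded with the
#'   outcome (the generating mechanism is identical, mirroring a binary
#'   2-year endpoint either way).
#' @param seed Master seed for the cohort.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 296,
                          prevalence_target = 52 / 296,
                          outcome_link_coefficients = c(log_mtv = 0.8,
                                                        suv_peak = 0.3,
                                                        dmax_bulk = 0.5),
                          link_intercept = NULL,
                          endpoint_mode = c("progression", "pfs"),
                          seed = 1L) {
  endpoint_mode <- match.arg(endpoint_mode)
  co <- as.numeric(outcome_link_coefficients)
  names(co) <- c("log_mtv", "suv_peak", "dmax_bulk")
  cfg <- list(n_patients = as.integer(n_patients),
              prevalence_target = prevalence_target,
              outcome_link_coefficients = co,
              link_intercept = link_intercept,
              endpoint_mode = endpoint_mode, seed = as.integer(seed))
  errs <- character()
  if (cfg$n_patients < 4) errs <- c(errs, "n_patients must be >= 4")
  if (!(prevalence_target > 0 && prevalence_target < 1))
    errs <- c(errs, "prevalence_target must be in (0, 1)")
  if (any(!is.finite(co))) errs <- c(errs, "outcome_link_coefficients must be finite")
  if (length(errs)) abort(paste(c("invalid cohort_config:", errs), collapse = "\n  "))
  structure(cfg, class = "cohort_config")
}

# uniform draw from an inclusive integer range (safe for degenerate ranges,
# unlike sample(x, ...) with scalar x)
sample_int_range <- function(rng, n) {
  vals <- seq.int(rng[1], rng[2])
  if (length(vals) == 1L) rep(vals, n) else sample(vals, n, replace = TRUE)
}

# pinned counter scheme for per-patient / per-stage seeds
derive_seed <- function(master, counter) {
  as.integer(((as.double(master) %% 65521) * 48271 + as.double(counter) * 10007) %% 2147483647)
}

#' Render one lesion into an SUV image
#'
#' Voxels whose (shape-scaled) distance `d` from the lesion center is at most
#' `radius_mm` are set to at least `peak_suv`; beyond the core the intensity
#' falls off as a Gaussian with a 1-voxel sigma. The lesion is combined with
#' the existing image by voxelwise maximum.
#'
#' @param image A [suv_image()].
#' @param center_mm Lesion center (mm, length 3).
#' @param radius_mm Core radius (mm).
#' @param peak_suv Core SUV.
#' @param shape `"sphere"`, `"ellipsoid"` or `"blob"`.
#' @param shape_params Optional list: `axes_scale` (length-3, ellipsoid axis
#'   scale factors, geometric mean 1) or `satellites` (matrix of relative
#'   offsets (mm) and radii for blob lobes).
#' @return The modified [suv_image()].
#' @export
render_lesion <- function(image, center_mm, radius_mm, peak_suv,
                          shape = c("sphere", "ellipsoid", "blob"),
                          shape_params = NULL) {
  shape <- match.arg(shape)
  res <- render_lesion_impl(image, center_mm, radius_mm, peak_suv, shape, shape_params)
  res$image
}

render_lesion_impl <- function(image, center_mm, radius_mm, peak_suv, shape,
                               shape_params = NULL, mtv_threshold = 4.0) {
  d <- dim(image$data)
  extent_lo <- image$origin
  extent_hi <- image$origin + (d - 1) * image$spacing
  if (any(center_mm - radius_mm < extent_lo) || any(center_mm + radius_mm > extent_hi)) {
    abort(sprintf("lesion core at center (%.1f, %.1f, %.1f) mm with radius %.1f mm extends outside the grid",
                  center_mm[1], center_mm[2], center_mm[3], radius_mm))
  }
  if (radius_mm < min(image$spacing)) abort("radius_mm must be at least one voxel")
  sigma <- mean(image$spacing)
  reach <- radius_mm + 3 * sigma
  # local crop
  lo <- pmax(1L, floor((center_mm - reach - image$origin) / image$spacing) + 1L)
  hi <- pmin(d, ceiling((center_mm + reach - image$origin) / image$spacing) + 1L)
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  xs <- image$origin[1] + (ii - 1) * image$spacing[1] - center_mm[1]
  ys <- image$origin[2] + (jj - 1) * image$spacing[2] - center_mm[2]
  zs <- image$origin[3] + (kk - 1) * image$spacing[3] - center_mm[3]

  eff_dist <- function(ax_scale, off = c(0, 0, 0)) {
    # distance in shape coordinates so that the iso-surface d = r encloses
    # the same volume as a radius-r sphere
    dx2 <- outer(outer(((xs - off[1]) / ax_scale[1])^2,
                       ((ys - off[2]) / ax_scale[2])^2, "+"),
                 ((zs - off[3]) / ax_scale[3])^2, "+")
    sqrt(dx2)
  }
  dist <- switch(shape,
    sphere = eff_dist(c(1, 1, 1)),
    ellipsoid = {
      ax <- shape_params$axes_scale %||% c(1.2, 1.0, 1 / 1.2)
      ax <- ax / prod(ax)^(1 / 3)
      eff_dist(ax)
    },
    blob = {
      sat <- shape_params$satellites %||%
        rbind(c(0.6 * radius_mm, 0, 0, 0.6 * radius_mm),
              c(0, 0.55 * radius_mm, 0.3 * radius_mm, 0.5 * radius_mm))
      dd <- eff_dist(c(1, 1, 1))
      for (s in seq_len(nrow(sat))) {
        # satellite with its own radius: rescale distance so core is at r
        ds <- eff_dist(c(1, 1, 1), off = sat[s, 1:3]) * (radius_mm / sat[s, 4])
        dd <- pmin(dd, ds)
      }
      dd
    })
  prof <- ifelse(dist <= radius_mm, 1, exp(-(dist - radius_mm)^2 / (2 * sigma^2)))
  lesion_val <- peak_suv * prof
  sub <- image$data[ii, jj, kk]
  image$data[ii, jj, kk] <- pmax(sub, lesion_val)
  list(image = image, core_voxels = sum(dist <= radius_mm),
       thr_voxels = sum(lesion_val >= mtv_threshold))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate one synthetic patient
#'
#' Draws a lesion count, log-uniform radii and peak SUVs, places lesion
#' centers uniformly with a margin from the grid edge, rejecting placements
#' that would overlap an existing lesion, and renders them onto a truncated
#' Gaussian background. Deterministic for a fixed `(config, seed)`.
#'
#' @param config A [phantom_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A list with elements `image` ([suv_image()]) and `truth` (a tibble
#'   with one row per lesion: center, radius, peak SUV and core volume).
#' @export
generate_patient <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(seed)
  d <- config$grid_shape
  img <- suv_image(array(0, d), spacing = config$spacing)
  sigma <- mean(config$spacing)
  extent_hi <- (d - 1) * config$spacing

  n_les <- sample_int_range(config$n_lesions_range, 1)
  rr <- config$lesion_radius_range_mm
  sr <- config$lesion_suv_range
  radii <- exp(runif(n_les, log(rr[1]), log(rr[2])))
  peaks <- exp(runif(n_les, log(sr[1]), log(sr[2])))
  # separation uses the super-threshold radius (core + visible rim) so that
  # rendered lesions stay disjoint components after thresholding
  r_eff <- radii + sigma * sqrt(2 * pmax(log(peaks / config$mtv_suv_threshold), 0))
  centers <- matrix(NA_real_, n_les, 3)
  placed_r <- numeric(0)
  for (l in seq_len(n_les)) {
    margin <- r_eff[l] + 3 * sigma
    if (any(extent_hi - 2 * margin <= 0)) {
      abort(sprintf("lesion radius %.1f mm cannot fit inside the %.0f x %.0f x %.0f mm grid",
                    radii[l], extent_hi[1], extent_hi[2], extent_hi[3]))
    }
    ok <- FALSE
    for (try in seq_len(200L)) {
      cand <- runif(3, margin, extent_hi - margin)
      if (l == 1L) { ok <- TRUE }
      else {
        dist_prev <- sqrt(colSums((t(centers[seq_len(l - 1), , drop = FALSE]) - cand)^2))
        ok <- all(dist_prev > r_eff[l] + placed_r + 2 * sigma)
      }
      if (ok) { centers[l, ] <- cand; break }
    }
    if (!ok) {
      abort(sprintf("could not place lesion %d (radius %.1f mm) without overlap after 200 tries",
                    l, radii[l]))
    }
    placed_r <- c(placed_r, r_eff[l])
  }

  # background: truncated Gaussian noise
  img$data[] <- pmax(rnorm(prod(d), config$background_suv, config$background_noise_sd), 0)
  core_vox <- integer(n_les); thr_vox <- integer(n_les)
  for (l in seq_len(n_les)) {
    sp <- if (config$lesion_shape == "ellipsoid") {
      list(axes_scale = exp(runif(3, log(0.75), log(1.3))))
    } else NULL
    res <- render_lesion_impl(img, centers[l, ], radii[l], peaks[l],
                              config$lesion_shape, sp,
                              mtv_threshold = config$mtv_suv_threshold)
    img <- res$image
    core_vox[l] <- res$core_voxels
    thr_vox[l] <- res$thr_voxels
  }
  truth <- tibble(
    lesion = seq_len(n_les),
    center_x_mm = centers[, 1], center_y_mm = centers[, 2], center_z_mm = centers[, 3],
    radius_mm = radii, peak_suv = peaks,
    # volume_ml: the lesion's rendered super-threshold volume (its true MTV
    # contribution); core_volume_ml: the uniform core only
    volume_ml = thr_vox * prod(config$spacing) / 1000,
    core_volume_ml = core_vox * prod(config$spacing) / 1000
  )
  list(image = img, truth = truth)
}

# ---- outcome link ----------------------------------------------------------

# true patient-level link features from a ground-truth lesion table
truth_link_features <- function(truth) {
  mtv <- sum(truth$volume_ml)
  bulk <- which.max(truth$volume_ml)
  cen <- as.matrix(truth[, c("center_x_mm", "center_y_mm", "center_z_mm")])
  dmax_bulk <- if (nrow(truth) == 1L) 0 else
    max(sqrt(colSums((t(cen) - cen[bulk, ])^2)))
  c(log_mtv = log(mtv), suv_peak = max(truth$peak_suv), dmax_bulk = dmax_bulk)
}

# Vectorized pilot sampler of true link features; ignores placement-overlap
# rejection (a second-order effect on the feature distribution) so that large
# pilot and Monte-Carlo draws stay cheap.
pilot_sample_features <- function(config, n, seed) {
  set.seed(seed)
  nmax <- config$n_lesions_range[2]
  nles <- sample_int_range(config$n_lesions_range, n)
  rr <- config$lesion_radius_range_mm; sr <- config$lesion_suv_range
  sigma <- mean(config$spacing)
  extent_hi <- (config$grid_shape - 1) * config$spacing
  active <- outer(seq_len(nmax), nles, function(j, m) j <= m)  # nmax x n
  radii <- matrix(exp(runif(n * nmax, log(rr[1]), log(rr[2]))), nmax, n)
  peaks <- matrix(exp(runif(n * nmax, log(sr[1]), log(sr[2]))), nmax, n)
  cen <- lapply(1:3, function(ax) {
    mar <- radii + 3 * sigma
    matrix(runif(n * nmax), nmax, n) * (extent_hi[ax] - 2 * mar) + mar
  })
  radii[!active] <- NA; peaks[!active] <- NA
  # analytic super-threshold radius: core plus the part of the Gaussian rim
  # at or above the MTV threshold
  thr <- config$mtv_suv_threshold
  r_eff <- radii + sigma * sqrt(2 * pmax(log(peaks / thr), 0))
  vols <- 4 / 3 * pi * r_eff^3 / 1000
  mtv <- colSums(vols, na.rm = TRUE)
  suv_peak <- apply(peaks, 2, max, na.rm = TRUE)
  vv <- vols; vv[is.na(vv)] <- -Inf
  bulk <- max.col(t(vv), ties.method = "first")
  dmax <- numeric(n)
  pick <- cbind(bulk, seq_len(n))
  d2 <- (t(cen[[1]]) - cen[[1]][pick])^2 +
        (t(cen[[2]]) - cen[[2]][pick])^2 +
        (t(cen[[3]]) - cen[[3]][pick])^2   # n x nmax
  d2[t(!active)] <- 0
  dmax <- sqrt(apply(d2, 1, max))
  cbind(log_mtv = log(mtv), suv_peak = suv_peak, dmax_bulk = dmax)
}

# pilot standardization + intercept calibration (pinned: 10,000 draws)
calibrate_link <- function(cohort, phantom, n_pilot = 10000L) {
  feats <- pilot_sample_features(phantom, n_pilot, derive_seed(cohort$seed, 0L))
  mu <- colMeans(feats); sdv <- apply(feats, 2, sd)
  sdv[sdv == 0] <- 1
  z <- sweep(sweep(feats, 2, mu), 2, sdv, "/")
  eta <- drop(z %*% cohort$outcome_link_coefficients)
  b0 <- if (!is.null(cohort$link_intercept)) cohort$link_intercept else
    stats::uniroot(function(b) mean(plogis(b + eta)) - cohort$prevalence_target,
                   c(-30, 30), tol = 1e-8)$root
  list(mu = mu, sd = sdv, intercept = b0)
}

#' Generate a synthetic cohort with linked binary outcome
#'
#' Generates `n_patients` phantom patients and draws each binary outcome from
#' `Bernoulli(plogis(intercept + coefficients %*% z))`, where `z` are the
#' patient's standardized true link features (log MTV, peak SUV, Dmax_bulk).
#' Standardization constants and (unless fixed) the intercept come from a
#' 10,000-draw pilot simulation, so the expected prevalence matches the
#' configured target. A degenerate all-one-class draw is regenerated with an
#' incremented seed (with a warning).
#'
#' @param cohort A [cohort_config()].
#' @param phantom A [phantom_config()].
#' @return A tibble with one row per patient: `patient_id`, list-columns
#'   `image` and `truth`, the true link features, `p_true`, `eta_true` (the
#'   linear predictor) and the binary `outcome`.
#' @export
generate_cohort <- function(cohort, phantom) {
  stopifnot(inherits(cohort, "cohort_config"), inherits(phantom, "phantom_config"))
  cal <- calibrate_link(cohort, phantom)
  seed <- cohort$seed
  for (attempt in seq_len(25L)) {
    n <- cohort$n_patients
    pats <- vector("list", n)
    feats <- matrix(NA_real_, n, 3, dimnames = list(NULL, names(cal$mu)))
    for (i in seq_len(n)) {
      # a rare unlucky draw can fail lesion placement; retry that patient
      # with a derived replacement seed rather than losing the cohort
      pat <- NULL
      for (sub in 0:19) {
        pat <- tryCatch(generate_patient(phantom, derive_seed(seed, i + sub * 600101L)),
                        error = function(e) NULL)
        if (!is.null(pat)) break
      }
      if (is.null(pat)) {
        abort(sprintf("patient %d: lesion placement failed for 20 derived seeds; the lesion size range does not fit the grid", i))
      }
      if (sub > 0) warn(sprintf("patient %d regenerated with a replacement seed after a placement failure", i))
      pats[[i]] <- pat
      feats[i, ] <- truth_link_features(pats[[i]]$truth)
    }
    z <- sweep(sweep(feats, 2, cal$mu), 2, cal$sd, "/")
    eta <- cal$intercept + drop(z %*% cohort$outcome_link_coefficients)
    set.seed(derive_seed(seed, 999983L))
    y <- rbinom(n, 1, plogis(eta))
    if (length(unique(y)) > 1L) {
      return(tibble(
        patient_id = seq_len(n),
        image = lapply(pats, `[[`, "image"),
        truth = lapply(pats, `[[`, "truth"),
        log_mtv = feats[, "log_mtv"], suv_peak = feats[, "suv_peak"],
        dmax_bulk = feats[, "dmax_bulk"],
        eta_true = eta, p_true = plogis(eta), outcome = y
      ))
    }
    warn(sprintf("cohort draw with seed %d produced a single outcome class; regenerating with seed %d",
                 seed, seed + 1L))
    seed <- seed + 1L
  }
  abort("failed to generate a two-class cohort after 25 seed increments")
}

#' Monte-Carlo Bayes AUC of the generating outcome model
#'
#' The AUC an oracle using the true linear predictor would achieve, estimated
#' by simulating `n_draws` patients from the ground-truth feature
#' distribution (no image rendering) and drawing their outcomes.
#'
#' @param cohort A [cohort_config()].
#' @param phantom A [phantom_config()].
#' @param n_draws Number of Monte-Carlo draws (simulated in chunks).
#' @param seed Seed for the simulation.
#' @return A single number in (0, 1).
#' @export
bayes_auc <- function(cohort, phantom, n_draws = 1e6, seed = 1L) {
  cal <- calibrate_link(cohort, phantom)
  chunk <- 1e5L
  etas <- list(); ys <- list()
  done <- 0L; ci <- 0L
  while (done < n_draws) {
    ci <- ci + 1L
    m <- as.integer(min(chunk, n_draws - done))
    feats <- pilot_sample_features(phantom, m, derive_seed(seed, ci))
    z <- sweep(sweep(feats, 2, cal$mu), 2, cal$sd, "/")
    eta <- cal$intercept + drop(z %*% cohort$outcome_link_coefficients)
    set.seed(derive_seed(seed, 5000L + ci))
    y <- rbinom(m, 1, plogis(eta))
    etas[[ci]] <- eta; ys[[ci]] <- y
    done <- done + m
  }
  auc_score(unlist(etas), unlist(ys))
}

#' Write a synthetic cohort to disk
#'
#' Writes each patient image as NIfTI and a `cohort.csv` with one row per
#' patient (id, outcome, true link features) plus a `lesions.csv` with the
#' per-lesion ground truth.
#'
#' @param cohort_tbl Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort_tbl, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(cohort_tbl))) {
    write_suv_image(cohort_tbl$image[[i]],
                    file.path(dir, sprintf("patient_%03d.nii.gz", cohort_tbl$patient_id[i])))
  }
  per_pat <- cohort_tbl %>% select(-"image", -"truth")
  utils::write.csv(per_pat, file.path(dir, "cohort.csv"), row.names = FALSE)
  lesions <- cohort_tbl %>%
    mutate(truth = .data$truth) %>%
    select("patient_id", "truth") %>%
    tidyr::unnest("truth")
  utils::write.csv(lesions, file.path(dir, "lesions.csv"), row.names = FALSE)
  invisible(dir)
}
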