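#' Lesion delineation by fixed SUV threshold with volume filtering
#'
#' Fully automated preselection of FDG-avid structures: 26-connected
#' components of voxels with SUV at or above `suv_threshold` are kept when
#' their volume reaches `min_volume_ml`. Labels are assigned in order of
#' decreasing volume (ties broken by lexicographic centroid order) so that
#' "lesion 1" is always the largest.
#'
#' @param image A [suv_image()].
#' @param suv_threshold SUV cut-off (inclusive), default 4.0.
#' @param min_volume_ml Minimum component volume in mL, default 3.0.
#' @return A `lesion_set`: list with `label_map` (integer array, 0 =
#'   background), `spacing`, `origin`, and `lesions`, a tibble of per-lesion
#'   summaries (voxel count, volume, centroid, SUVmax, SUVmean, SUVpeak).
#' @export
delineate <- function(image, suv_threshold = 4.0, min_volume_ml = 3.0) {
  stopifnot(inherits(image, "suv_image"))
  if (any(!is.finite(image$data))) abort("image contains non-finite voxels")
  mask <- image$data >= suv_threshold
  vox_ml <- voxel_volume_ml(image)
  lab <- label_components_3d(mask, connectivity = 26)
  keep_map <- integer(0)
  if (any(lab > 0)) {
    counts <- tabulate(lab[lab > 0])
    keep <- which(counts * vox_ml >= min_volume_ml)
    keep_map <- keep
  }
  new_lab <- array(0L, dim(image$data))
  for (new_id in seq_along(keep_map)) {
    new_lab[lab == keep_map[new_id]] <- new_id
  }
  les <- new_lesion_set(new_lab, image)
  les
}

# build a lesion_set from a raw label map: summarise, order by volume
new_lesion_set <- function(label_map, image) {
  sm <- summarize_lesions(image, label_map)
  # reorder labels by decreasing volume, ties by centroid lexicographic order
  if (nrow(sm) > 0) {
    ord <- order(-sm$volume_ml, sm$centroid_x_mm, sm$centroid_y_mm, sm$centroid_z_mm)
    relabel <- integer(nrow(sm))
    relabel[sm$lesion[ord]] <- seq_len(nrow(sm))
    lm2 <- label_map
    nz <- label_map > 0
    lm2[nz] <- relabel[label_map[nz]]
    label_map <- lm2
    sm <- sm[ord, , drop = FALSE]
    sm$lesion <- seq_len(nrow(sm))
  }
  structure(list(label_map = label_map, spacing = image$spacing,
                 origin = image$origin, lesions = sm),
            class = "lesion_set")
}

#' Recompute per-lesion summaries from a label map and image
#'
#' @param image A [suv_image()].
#' @param label_map Integer array with 0 background and positive lesion labels.
#' @return A tibble with one row per label.
#' @export
summarize_lesions <- function(image, label_map) {
  idx <- which(label_map > 0)
  if (length(idx) == 0L) {
    return(tibble(lesion = integer(), n_voxels = integer(), volume_ml = numeric(),
                  centroid_x_mm = numeric(), centroid_y_mm = numeric(),
                  centroid_z_mm = numeric(), suv_max = numeric(),
                  suv_mean = numeric(), suv_peak = numeric()))
  }
  labs <- label_map[idx]
  vox_ml <- voxel_volume_ml(image)
  ai <- arrayInd(idx, dim(label_map))
  cen <- voxel_centers_mm(image, ai)
  suv <- image$data[idx]
  offs <- sphere_offsets(image$spacing, 1)
  pk <- sphere_mean_at(image$data, ai, offs)
  ids <- sort(unique(labs))
  tibble(
    lesion = ids,
    n_voxels = as.integer(tapply(labs, labs, length)[as.character(ids)]),
    volume_ml = as.numeric(tapply(labs, labs, length)[as.character(ids)]) * vox_ml,
    centroid_x_mm = as.numeric(tapply(cen[, 1], labs, mean)[as.character(ids)]),
    centroid_y_mm = as.numeric(tapply(cen[, 2], labs, mean)[as.character(ids)]),
    centroid_z_mm = as.numeric(tapply(cen[, 3], labs, mean)[as.character(ids)]),
    suv_max = as.numeric(tapply(suv, labs, max)[as.character(ids)]),
    suv_mean = as.numeric(tapply(suv, labs, mean)[as.character(ids)]),
    suv_peak = as.numeric(tapply(pk, labs, max)[as.character(ids)])
  )
}

#' @export
print.lesion_set <- function(x, ...) {
  cat(sprintf("<lesion_set> %d lesion(s), total MTV %.2f mL\n",
              nrow(x$lesions), sum(x$lesions$volume_ml)))
  if (nrow(x$lesions)) print(x$lesions)
  invisible(x)
}

#' Add a sub-threshold-volume lesion from a seed voxel
#'
#' Emulates the single-click addition of small lymphoma lesions: the
#' 26-connected above-threshold component containing `seed_voxel` is added to
#' the lesion set regardless of its volume. Seeding inside an existing lesion
#' leaves the set unchanged.
#'
#' @param lesions A `lesion_set`.
#' @param image The [suv_image()] the set was delineated from.
#' @param seed_voxel Integer voxel index (i, j, k).
#' @param suv_threshold SUV cut-off used to grow the component.
#' @return An updated `lesion_set` with labels renumbered by volume.
#' @export
add_lesion <- function(lesions, image, seed_voxel, suv_threshold = 4.0) {
  stopifnot(inherits(lesions, "lesion_set"), inherits(image, "suv_image"))
  seed_voxel <- as.integer(seed_voxel)
  sv <- image$data[seed_voxel[1], seed_voxel[2], seed_voxel[3]]
  if (sv < suv_threshold) {
    abort(sprintf("seed voxel (%d, %d, %d) has SUV %.2f, below the %.1f threshold",
                  seed_voxel[1], seed_voxel[2], seed_voxel[3], sv, suv_threshold))
  }
  if (lesions$label_map[seed_voxel[1], seed_voxel[2], seed_voxel[3]] > 0) {
    return(lesions)   # already part of a lesion
  }
  mask <- image$data >= suv_threshold
  lab <- label_components_3d(mask, connectivity = 26)
  comp <- lab[seed_voxel[1], seed_voxel[2], seed_voxel[3]]
  new_map <- lesions$label_map
  new_id <- max(0L, new_map) + 1L
  new_map[lab == comp & new_map == 0L] <- new_id
  new_lesion_set(new_map, image)
}

#' Remove a lesion from a lesion set
#'
#' Emulates manual removal of non-tumor FDG-avid regions. Remaining labels
#' are renumbered by decreasing volume.
#'
#' @param lesions A `lesion_set`.
#' @param lesion_id Label of the lesion to remove.
#' @return An updated `lesion_set`.
#' @export
remove_region <- function(lesions, lesion_id) {
  stopifnot(inherits(lesions, "lesion_set"))
  if (!lesion_id %in% lesions$lesions$lesion) {
    abort(sprintf("no lesion with id %s (available: %s)", lesion_id,
                  paste(lesions$lesions$lesion, collapse = ", ")))
  }
  keep <- lesions$lesions %>% filter(.data$lesion != lesion_id)
  old_ids <- keep$lesion
  new_map <- array(0L, dim(lesions$label_map))
  for (r in seq_along(old_ids)) {
    new_map[lesions$label_map == old_ids[r]] <- r
  }
  keep$lesion <- seq_len(nrow(keep))
  structure(list(label_map = new_map, spacing = lesions$spacing,
                 origin = lesions$origin, lesions = keep),
            class = "lesion_set")
}

#' Scan quality control verdict
#'
#' A scan passes when mean hepatic SUV lies in `[1.3, 3.0]` and plasma
#' glucose is below 11 mmol/L. A scan with out-of-range hepatic SUV is still
#' accepted when the image contains between 50 and 80 percent of the injected
#' FDG activity (verdict `pass_by_activity`); otherwise it fails.
#'
#' @param hepatic_suv_mean Mean hepatic SUV.
#' @param plasma_glucose Plasma glucose (mmol/L).
#' @param image_activity_fraction Fraction of injected activity in the image
#'   (may be `NA` when hepatic SUV is in range).
#' @return A one-row tibble: inputs, `verdict`
#'   (`pass` / `pass_by_activity` / `fail`) and `reason`.
#' @export
check_scan_quality <- function(hepatic_suv_mean, plasma_glucose,
                               image_activity_fraction = NA_real_) {
  vals <- c(hepatic_suv_mean, plasma_glucose)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("hepatic_suv_mean and plasma_glucose must be finite and non-negative")
  }
  hepatic_ok <- hepatic_suv_mean >= 1.3 && hepatic_suv_mean <= 3.0
  glucose_ok <- plasma_glucose < 11
  activity_ok <- is.finite(image_activity_fraction) &&
    image_activity_fraction >= 0.50 && image_activity_fraction <= 0.80
  if (hepatic_ok && glucose_ok) {
    verdict <- "pass"; reason <- "hepatic SUV and glucose within range"
  } else if (!hepatic_ok && glucose_ok && activity_ok) {
    verdict <- "pass_by_activity"
    reason <- "hepatic SUV out of range but 50-80% of injected activity in image"
  } else {
    verdict <- "fail"
    reason <- paste(c(
      if (!hepatic_ok) sprintf("hepatic SUV %.2f outside [1.3, 3.0]", hepatic_suv_mean),
      if (!glucose_ok) sprintf("plasma glucose %.1f >= 11 mmol/L", plasma_glucose),
      if (!hepatic_ok && glucose_ok && !activity_ok)
        "image activity fraction outside [0.50, 0.80]"
    ), collapse = "; ")
  }
  tibble(hepatic_suv_mean = hepatic_suv_mean, plasma_glucose = plasma_glucose,
         image_activity_fraction = image_activity_fraction,
         verdict = verdict, reason = reason)
}
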