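#' Extract the full radiomics panel for lesions or the patient VOI
#'
#' Per VOI: 5 conventional PET features on the original grid, then, after
#' cropping a padded neighbourhood, resampling to 2 x 2 x 2 mm and fixed-bin
#' 0.25-SUV discretization, 22 morphology, 50 intensity and 408 texture
#' features (485 in total). At `level = "patient_voi"` the multi-lesion
#' union is treated as a single, possibly disconnected VOI.
#'
#' @param image A [suv_image()].
#' @param lesions A `lesion_set` with at least one lesion.
#' @param level `"per_lesion"` (one row per lesion) or `"patient_voi"` (one
#'   row for the union).
#' @param bin_width,anchor Discretization parameters (SUV).
#' @param resample_spacing Target spacing in mm.
#' @return A tibble with a `lesion` id column (0 for the patient VOI) and
#'   485 feature columns prefixed `conv_` / `morph_` / `int_` / `tex_`.
#' @export
extract_panel <- function(image, lesions, level = c("per_lesion", "patient_voi"),
                          bin_width = 0.25, anchor = 0.0,
                          resample_spacing = c(2, 2, 2)) {
  level <- match.arg(level)
  stopifnot(inherits(image, "suv_image"), inherits(lesions, "lesion_set"))
  if (nrow(lesions$lesions) < 1) abort("lesion set is empty")
  voi_ids <- if (level == "per_lesion") lesions$lesions$lesion else 0L
  rows <- lapply(voi_ids, function(id) {
    mask <- if (id == 0L) lesions$label_map > 0 else lesions$label_map == id
    extract_voi_features(image, mask, bin_width, anchor, resample_spacing)
  })
  out <- bind_cols(tibble(lesion = as.integer(voi_ids)), bind_rows(rows))
  assert_panel_counts(out)
  out
}

# single-VOI feature vector (1 x 485 tibble)
extract_voi_features <- function(image, mask, bin_width = 0.25, anchor = 0.0,
                                 resample_spacing = c(2, 2, 2)) {
  conv <- conventional_pet(image, mask)
  # crop a padded neighbourhood (>= 1-mL-sphere radius, plus interpolation
  # support) before resampling
  pad <- pmax(2L, as.integer(ceiling(8 / image$spacing)))
  rng <- bbox_ranges(mask, pad = max(pad))
  sub <- image$data[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  sub <- array(sub, c(length(rng[[1]]), length(rng[[2]]), length(rng[[3]])))
  sub_mask <- array(mask[rng[[1]], rng[[2]], rng[[3]]], dim(sub))
  sub_img <- suv_image(sub, spacing = image$spacing,
                       origin = image$origin + (c(rng[[1]][1], rng[[2]][1], rng[[3]][1]) - 1) * image$spacing)
  vol <- resample_volume(sub_img, sub_mask, spacing = resample_spacing)
  disc <- discretize(vol, bin_width = bin_width, anchor = anchor)
  bind_cols(conv, morphology_features(vol), intensity_features(vol, disc),
            texture_features(disc))
}

# category-count contract: 5 conventional, 22 morphology, 50 intensity,
# 408 texture
assert_panel_counts <- function(tbl) {
  counts <- c(conv = sum(startsWith(names(tbl), "conv_")),
              morph = sum(startsWith(names(tbl), "morph_")),
              int = sum(startsWith(names(tbl), "int_")),
              tex = sum(startsWith(names(tbl), "tex_")))
  expected <- c(conv = 5L, morph = 22L, int = 50L, tex = 408L)
  if (!identical(as.integer(counts), as.integer(expected))) {
    abort(sprintf("panel category counts %s do not match the pinned 5/22/50/408",
                  paste(counts, collapse = "/")))
  }
  invisible(tbl)
}

# names of the 480 radiomics (morphology + intensity + texture) columns
radiomics_cols <- function(tbl) {
  names(tbl)[startsWith(names(tbl), "morph_") | startsWith(names(tbl), "int_") |
             startsWith(names(tbl), "tex_")]
}

#' Extract features for a whole synthetic cohort
#'
#' Runs delineation and feature extraction over a [generate_cohort()] tibble
#' and collects the tables the lesion/feature-selection approaches draw
#' from. Ground-truth lesions missed by the automated preselection (volume
#' below the 3-mL cut-off) are added back via [add_lesion()] seeded at the
#' true lesion center, emulating the manual click-to-add step of the
#' clinical workflow.
#'
#' @param cohort_tbl Result of [generate_cohort()].
#' @param suv_threshold,min_volume_ml Delineation parameters.
#' @param panels Character subset of
#'   `c("conventional", "dissemination", "radiomics_patient", "radiomics_lesion")`;
#'   restricting the set skips expensive extractions models do not need.
#' @param add_missed_lesions Add back sub-threshold-volume true lesions.
#' @param verbose Print one line per 25 patients.
#' @return A `cohort_features` list of tibbles: `patients` (id + outcome),
#'   `conventional`, `dissemination`, `patient_radiomics` (480 columns),
#'   `lesion_radiomics` (per-lesion 480 columns plus volume and SUVmax),
#'   and `lesion_summaries`.
#' @export
extract_cohort_features <- function(cohort_tbl,
                                    suv_threshold = 4.0, min_volume_ml = 3.0,
                                    panels = c("conventional", "dissemination",
                                               "radiomics_patient", "radiomics_lesion"),
                                    add_missed_lesions = TRUE,
                                    verbose = FALSE) {
  panels <- match.arg(panels, several.ok = TRUE)
  n <- nrow(cohort_tbl)
  conv <- vector("list", n); diss <- vector("list", n)
  prad <- vector("list", n); lrad <- vector("list", n); lsum <- vector("list", n)
  for (i in seq_len(n)) {
    img <- cohort_tbl$image[[i]]
    ls <- delineate(img, suv_threshold, min_volume_ml)
    if (add_missed_lesions && !is.null(cohort_tbl$truth[[i]])) {
      tr <- cohort_tbl$truth[[i]]
      for (l in seq_len(nrow(tr))) {
        ctr <- c(tr$center_x_mm[l], tr$center_y_mm[l], tr$center_z_mm[l])
        vox <- pmin(pmax(round((ctr - img$origin) / img$spacing) + 1, 1), dim(img$data))
        if (ls$label_map[vox[1], vox[2], vox[3]] == 0 &&
            img$data[vox[1], vox[2], vox[3]] >= suv_threshold) {
          ls <- add_lesion(ls, img, vox, suv_threshold)
        }
      }
    }
    if (nrow(ls$lesions) == 0) {
      abort(sprintf("patient %d has no delineable lesion", cohort_tbl$patient_id[i]))
    }
    pid <- tibble(patient_id = cohort_tbl$patient_id[i])
    lsum[[i]] <- bind_cols(pid, ls$lesions)
    if ("conventional" %in% panels) {
      conv[[i]] <- bind_cols(pid, conventional_pet(img, ls))
    }
    if ("dissemination" %in% panels) {
      diss[[i]] <- bind_cols(pid, dissemination_features(ls))
    }
    if ("radiomics_patient" %in% panels) {
      pv <- extract_panel(img, ls, "patient_voi")
      prad[[i]] <- bind_cols(pid, pv[, radiomics_cols(pv)])
    }
    if ("radiomics_lesion" %in% panels) {
      pl <- extract_panel(img, ls, "per_lesion")
      lrad[[i]] <- bind_cols(pid,
                             ls$lesions[, c("lesion", "volume_ml", "suv_max")],
                             pl[, radiomics_cols(pl)])
    }
    if (verbose && i %% 25 == 0) message(sprintf("  extracted %d / %d patients", i, n))
  }
  structure(list(
    patients = tibble(patient_id = cohort_tbl$patient_id, outcome = cohort_tbl$outcome),
    conventional = if ("conventional" %in% panels) bind_rows(conv) else NULL,
    dissemination = if ("dissemination" %in% panels) bind_rows(diss) else NULL,
    patient_radiomics = if ("radiomics_patient" %in% panels) bind_rows(prad) else NULL,
    lesion_radiomics = if ("radiomics_lesion" %in% panels) bind_rows(lrad) else NULL,
    lesion_summaries = bind_rows(lsum)
  ), class = "cohort_features")
}
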