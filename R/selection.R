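#' The twelve lesion/feature-selection approaches
#'
#' @return Character vector of valid approach ids: the reference model (MTV,
#'   SUVpeak, Dmax_bulk), five lesion-selection variants (largest, hottest,
#'   patient-level MTV, maximum- and median-aggregated), the dissemination
#'   model, and the dissemination + radiomics combinations (the last two,
#'   `diss_maximum` and `diss_median`, are the exploratory ones).
#' @export
petrad_approaches <- function() {
  c("reference", "largest", "hottest", "patient_mtv", "maximum", "median",
    "dissemination", "diss_patient_mtv", "diss_largest", "diss_hottest",
    "diss_maximum", "diss_median")
}

#' Model specification: approach + preprocessing choices
#'
#' @param approach One of [petrad_approaches()].
#' @param oversampling `"none"` or `"interpolate"` (SMOTE in training folds).
#' @param reduction One of `"none"`, `"pca"`, `"fa"`, `"rfe_rf"`,
#'   `"rfe_svm"`, `"rfe_lr"`, `"anova_top10pct"`.
#' @return A `model_spec` list.
#' @export
model_spec <- function(approach,
                       oversampling = c("none", "interpolate"),
                       reduction = c("none", "pca", "fa", "rfe_rf", "rfe_svm",
                                     "rfe_lr", "anova_top10pct")) {
  if (!approach %in% petrad_approaches()) {
    abort(sprintf("unknown approach '%s'; valid ids: %s", approach,
                  paste(petrad_approaches(), collapse = ", ")))
  }
  oversampling <- match.arg(oversampling)
  reduction <- match.arg(reduction)
  structure(list(approach = approach, oversampling = oversampling,
                 reduction = reduction), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s | oversampling: %s | reduction: %s\n",
              x$approach, x$oversampling, x$reduction))
  invisible(x)
}

#' Select the largest or hottest lesion
#'
#' Largest = maximum volume; hottest = maximum SUVmax. Ties are broken by
#' volume and then by label order, which is itself deterministic
#' (volume-then-centroid).
#'
#' @param lesions A `lesion_set` with at least one lesion.
#' @return A lesion id.
#' @export
select_largest <- function(lesions) {
  sm <- lesions$lesions
  if (nrow(sm) < 1) abort("lesion set is empty")
  sm$lesion[order(-sm$volume_ml, sm$lesion)][1]
}

#' @rdname select_largest
#' @export
select_hottest <- function(lesions) {
  sm <- lesions$lesions
  if (nrow(sm) < 1) abort("lesion set is empty")
  sm$lesion[order(-sm$suv_max, -sm$volume_ml, sm$lesion)][1]
}

#' Aggregate per-lesion feature vectors
#'
#' Elementwise maximum or median across a patient's lesions, applied to the
#' 480 radiomics features.
#'
#' @param lesion_tbl A tibble of per-lesion feature rows with identical
#'   columns.
#' @param how `"maximum"` or `"median"`.
#' @return A one-row tibble.
#' @export
aggregate_lesions <- function(lesion_tbl, how = c("maximum", "median")) {
  how <- match.arg(how)
  f <- if (how == "maximum") max else median
  summarise(lesion_tbl, across(dplyr::everything(), f))
}

#' Build the modeling feature table for one approach
#'
#' Assembles a patients x features tibble for the given [model_spec()] (or
#' approach id). Column-count contract, asserted on construction:
#' reference 3; largest / hottest / patient_mtv / maximum / median 485
#' (480 radiomics + 5 conventional); dissemination 23 (18 + 5); `diss_*`
#' combinations 503 (498 radiomics + 5 conventional). Conventional PET
#' features are always the patient-level ones.
#'
#' @param features A [extract_cohort_features()] result.
#' @param spec A [model_spec()] or approach id string.
#' @return A tibble with `patient_id`, `outcome` and the feature columns.
#' @export
build_feature_table <- function(features, spec) {
  stopifnot(inherits(features, "cohort_features"))
  if (is.character(spec)) spec <- model_spec(spec)
  ap <- spec$approach
  need <- function(part) {
    if (is.null(features[[part]])) {
      abort(sprintf("approach '%s' needs the '%s' panel, which was not extracted", ap, part))
    }
    features[[part]]
  }
  base <- features$patients
  conv5 <- need("conventional")

  pick_lesion <- function(selector) {
    lr <- need("lesion_radiomics")
    sel <- features$lesion_summaries %>%
      group_by(.data$patient_id) %>%
      dplyr::group_modify(function(d, g) {
        ls <- list(lesions = d)
        class(ls) <- "lesion_set"
        tibble(lesion = selector(ls))
      }) %>% ungroup()
    lr %>% dplyr::inner_join(sel, by = c("patient_id", "lesion")) %>%
      select(-"lesion", -"volume_ml", -"suv_max")
  }
  agg_lesions <- function(how) {
    lr <- need("lesion_radiomics")
    cols <- setdiff(names(lr), c("patient_id", "lesion", "volume_ml", "suv_max"))
    lr %>% group_by(.data$patient_id) %>%
      summarise(across(all_of(cols), if (how == "maximum") max else median)) %>%
      ungroup()
  }

  radiomics <- switch(ap,
    reference = NULL,
    largest = pick_lesion(select_largest),
    hottest = pick_lesion(select_hottest),
    patient_mtv = need("patient_radiomics"),
    maximum = agg_lesions("maximum"),
    median = agg_lesions("median"),
    dissemination = NULL,
    diss_patient_mtv = need("patient_radiomics"),
    diss_largest = pick_lesion(select_largest),
    diss_hottest = pick_lesion(select_hottest),
    diss_maximum = agg_lesions("maximum"),
    diss_median = agg_lesions("median"))

  with_diss <- ap == "dissemination" || startsWith(ap, "diss_")
  tbl <- base
  if (ap == "reference") {
    diss <- need("dissemination")
    tbl <- tbl %>%
      dplyr::inner_join(conv5 %>% select("patient_id", "conv_mtv_ml", "conv_suv_peak"),
                        by = "patient_id") %>%
      dplyr::inner_join(diss %>% select("patient_id", "diss_dmax_bulk"),
                        by = "patient_id")
  } else {
    tbl <- tbl %>% dplyr::inner_join(conv5, by = "patient_id")
    if (with_diss) {
      tbl <- tbl %>% dplyr::inner_join(need("dissemination"), by = "patient_id")
    }
    if (!is.null(radiomics)) {
      tbl <- tbl %>% dplyr::inner_join(radiomics, by = "patient_id")
    }
  }
  n_feat <- ncol(tbl) - 2L
  expected <- switch(ap,
    reference = 3L,
    largest = , hottest = , patient_mtv = , maximum = , median = 485L,
    dissemination = 23L,
    503L)
  if (n_feat != expected) {
    abort(sprintf("approach '%s' produced %d feature columns, expected %d",
                  ap, n_feat, expected))
  }
  if (anyNA(tbl)) abort("feature table contains missing values")
  tbl
}

#' Largest-vs-hottest lesion concordance
#'
#' Fraction of patients whose largest and hottest lesion are the same
#' lesion, plus a breakdown of the mismatches by the size (volume < 10 mL)
#' and intensity (SUVpeak < 10) of the largest lesion.
#'
#' @param features A [extract_cohort_features()] result (the lesion
#'   summaries are used).
#' @return A list: `concordance` (fraction in `[0, 1]`), `n_patients`,
#'   `n_mismatch` and `breakdown`, a tibble partitioning the mismatches into
#'   small-largest-lesion, low-intensity-largest-lesion, and other.
#' @export
lesion_concordance <- function(features) {
  stopifnot(inherits(features, "cohort_features"))
  per_pat <- features$lesion_summaries %>%
    group_by(.data$patient_id) %>%
    dplyr::group_modify(function(d, g) {
      ls <- structure(list(lesions = d), class = "lesion_set")
      big <- select_largest(ls)
      hot <- select_hottest(ls)
      tibble(match = big == hot,
             largest_volume_ml = d$volume_ml[d$lesion == big],
             largest_suv_peak = d$suv_peak[d$lesion == big])
    }) %>% ungroup()
  mm <- per_pat %>% filter(!.data$match)
  breakdown <- tibble(
    category = c("largest_volume_lt_10ml", "largest_suv_peak_lt_10", "other"),
    n = c(sum(mm$largest_volume_ml < 10),
          sum(mm$largest_volume_ml >= 10 & mm$largest_suv_peak < 10),
          sum(mm$largest_volume_ml >= 10 & mm$largest_suv_peak >= 10))
  )
  list(concordance = mean(per_pat$match), n_patients = nrow(per_pat),
       n_mismatch = nrow(mm), breakdown = breakdown)
}
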