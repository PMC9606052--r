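#' Experiment configuration
#'
#' Bundles phantom, cohort, delineation, model grid and CV settings for
#' [run_experiment()]. Round-trips losslessly through YAML via
#' [write_experiment_config()] / [validate_config()].
#'
#' @param phantom A [phantom_config()].
#' @param cohort A [cohort_config()].
#' @param approaches Approach ids to evaluate (default: all 12).
#' @param oversampling_options Subset of `c("none", "interpolate")`.
#' @param reduction_options Subset of the 7 reduction method names.
#' @param n_folds,n_repeats CV geometry.
#' @param suv_threshold,min_volume_ml Delineation parameters.
#' @param num_trees Random forest size for `rfe_rf` and importances.
#' @param seed Master seed for the whole experiment.
#' @param out_dir Optional output directory for the report CSVs.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(phantom = phantom_config(),
                              cohort = cohort_config(),
                              approaches = petrad_approaches(),
                              oversampling_options = c("none", "interpolate"),
                              reduction_options = c("none", "pca", "fa", "rfe_rf",
                                                    "rfe_svm", "rfe_lr",
                                                    "anova_top10pct"),
                              n_folds = 5, n_repeats = 50,
                              suv_threshold = 4.0, min_volume_ml = 3.0,
                              num_trees = 500L,
                              seed = 1L, out_dir = NULL) {
  cfg <- list(schema_version = 1L,
              phantom = unclass(phantom), cohort = unclass(cohort),
              approaches = approaches,
              oversampling_options = oversampling_options,
              reduction_options = reduction_options,
              n_folds = as.integer(n_folds), n_repeats = as.integer(n_repeats),
              suv_threshold = suv_threshold, min_volume_ml = min_volume_ml,
              num_trees = as.integer(num_trees),
              seed = as.integer(seed), out_dir = out_dir)
  validate_config(cfg)
}

#' Validate an experiment configuration
#'
#' Accepts an `experiment_config`, a plain list, or a path to a YAML file;
#' checks every field and reports all violations at once.
#'
#' @param x Config object, list, or YAML path.
#' @return The validated `experiment_config`.
#' @export
validate_config <- function(x) {
  if (is.character(x)) {
    if (!file.exists(x)) abort(sprintf("config file '%s' does not exist", x))
    x <- tryCatch(yaml::read_yaml(x),
                  error = function(e) abort(sprintf("cannot parse config: %s",
                                                    conditionMessage(e))))
  }
  errs <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  ph <- x$phantom; co <- x$cohort
  chk(is.list(ph), "missing phantom section")
  chk(is.list(co), "missing cohort section")
  phantom <- tryCatch(do.call(phantom_config, ph[intersect(names(ph), names(formals(phantom_config)))]),
                      error = function(e) { errs <<- c(errs, conditionMessage(e)); NULL })
  cohort <- tryCatch({
    args <- co[intersect(names(co), names(formals(cohort_config)))]
    if (!is.null(args$outcome_link_coefficients)) {
      args$outcome_link_coefficients <- unlist(args$outcome_link_coefficients)
    }
    do.call(cohort_config, args)
  }, error = function(e) { errs <<- c(errs, conditionMessage(e)); NULL })
  bad_ap <- setdiff(x$approaches, petrad_approaches())
  chk(length(bad_ap) == 0,
      sprintf("unknown approach id(s) %s; valid ids: %s",
              paste(bad_ap, collapse = ", "),
              paste(petrad_approaches(), collapse = ", ")))
  chk(length(x$approaches) >= 1, "at least one approach required")
  chk(all(x$oversampling_options %in% c("none", "interpolate")),
      "oversampling_options must be a subset of {none, interpolate}")
  chk(all(x$reduction_options %in% c("none", "pca", "fa", "rfe_rf", "rfe_svm",
                                     "rfe_lr", "anova_top10pct")),
      "invalid reduction_options")
  chk(is.numeric(x$n_folds) && x$n_folds >= 2, "n_folds must be >= 2")
  chk(is.numeric(x$n_repeats) && x$n_repeats >= 1, "n_repeats must be >= 1")
  chk(is.numeric(x$suv_threshold) && x$suv_threshold > 0, "suv_threshold must be > 0")
  chk(is.numeric(x$min_volume_ml) && x$min_volume_ml >= 0, "min_volume_ml must be >= 0")
  chk(is.numeric(x$seed), "seed must be numeric")
  if (length(errs)) {
    abort(paste(c("invalid experiment config:", errs), collapse = "\n  "))
  }
  structure(list(schema_version = 1L, phantom = phantom, cohort = cohort,
                 approaches = x$approaches,
                 oversampling_options = x$oversampling_options,
                 reduction_options = x$reduction_options,
                 n_folds = as.integer(x$n_folds), n_repeats = as.integer(x$n_repeats),
                 suv_threshold = x$suv_threshold, min_volume_ml = x$min_volume_ml,
                 num_trees = as.integer(x$num_trees %||% 500L),
                 seed = as.integer(x$seed), out_dir = x$out_dir),
            class = "experiment_config")
}

#' Write an experiment configuration to YAML
#'
#' @param config An `experiment_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_experiment_config <- function(config, path) {
  plain <- rapply(unclass(config), unclass, how = "replace")
  yaml::write_yaml(plain, path, precision = 15)
  invisible(path)
}

#' Run the full model-comparison experiment on a synthetic cohort
#'
#' End-to-end driver: generates the cohort, delineates lesions, extracts the
#' feature panels the configured approaches need, evaluates every
#' approach x oversampling x reduction grid cell with repeated stratified
#' CV (shared fold assignments), selects the best cell per approach by mean
#' CV-AUC, and computes the largest-vs-hottest concordance statistic, the
#' Pearson correlation of Dmax_bulk with MTV, and random-forest feature
#' importances for each approach's best non-PCA reduction.
#'
#' @param config An `experiment_config` (or YAML path).
#' @param verbose Print stage progress.
#' @return An `experiment_report`: tibbles `grid` (all cells), `best` (one
#'   row per approach), `concordance`, `dmax_mtv_correlation`, a named list
#'   `importance`, and `provenance` (seed, config hash, timestamps). When
#'   `config$out_dir` is set the tables are also written as CSV.
#' @export
run_experiment <- function(config, verbose = TRUE) {
  config <- validate_config(config)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      abort(sprintf("experiment stage '%s' failed: %s", name, conditionMessage(e)))
    })
    say("stage %-12s %6.1f s", name, as.numeric(Sys.time() - t0, units = "secs"))
    res
  }
  cohort_tbl <- stage("cohort", generate_cohort(config$cohort, config$phantom))

  needed <- c("conventional", "dissemination")
  if (any(config$approaches %in% c("patient_mtv", "diss_patient_mtv"))) {
    needed <- c(needed, "radiomics_patient")
  }
  if (any(config$approaches %in% c("largest", "hottest", "maximum", "median",
                                   "diss_largest", "diss_hottest",
                                   "diss_maximum", "diss_median"))) {
    needed <- c(needed, "radiomics_lesion")
  }
  features <- stage("features",
                    extract_cohort_features(cohort_tbl, config$suv_threshold,
                                            config$min_volume_ml, panels = needed))

  y <- features$patients$outcome
  folds <- lapply(seq_len(config$n_repeats),
                  function(r) stratified_folds(y, config$n_folds,
                                               derive_seed(config$seed, r)))
  grid <- tidyr::expand_grid(approach = config$approaches,
                             oversampling = config$oversampling_options,
                             reduction = config$reduction_options)
  cells <- stage("cv-grid", {
    purrr::pmap(grid, function(approach, oversampling, reduction) {
      spec <- model_spec(approach, oversampling, reduction)
      tbl <- build_feature_table(features, spec)
      cv <- run_repeated_cv(tbl, spec, config$n_folds, config$n_repeats,
                            seed = config$seed, folds = folds,
                            num_trees = config$num_trees)
      tibble(approach = approach, oversampling = oversampling,
             reduction = reduction, mean_cv_auc = cv$mean_auc,
             sd_cv_auc = cv$sd_auc, n_fold_aucs = nrow(cv$aucs))
    }) %>% bind_rows()
  })
  best <- cells %>% group_by(.data$approach) %>%
    arrange(desc(.data$mean_cv_auc), .data$oversampling, .data$reduction) %>%
    dplyr::slice(1) %>% ungroup()

  conc <- lesion_concordance(features)
  dmax_mtv_r <- cor(features$dissemination$diss_dmax_bulk,
                    features$conventional$conv_mtv_ml)

  importance <- stage("importance", {
    imps <- list()
    for (ap in config$approaches) {
      cand <- cells %>% filter(.data$approach == ap, .data$reduction != "pca") %>%
        arrange(desc(.data$mean_cv_auc))
      if (nrow(cand) == 0) next
      spec <- model_spec(ap, cand$oversampling[1], cand$reduction[1])
      tbl <- build_feature_table(features, spec)
      imps[[ap]] <- feature_importance(tbl, spec, seed = config$seed,
                                       num_trees = config$num_trees)
    }
    imps
  })

  report <- structure(list(
    grid = cells, best = best,
    concordance = conc, dmax_mtv_correlation = dmax_mtv_r,
    importance = importance,
    provenance = list(seed = config$seed,
                      config_hash = rlang::hash(unclass(config)),
                      n_patients = nrow(cohort_tbl),
                      prevalence = mean(y),
                      generated_at = "run_experiment")
  ), class = "experiment_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(report$grid, file.path(config$out_dir, "grid.csv"), row.names = FALSE)
    utils::write.csv(report$best, file.path(config$out_dir, "best_models.csv"), row.names = FALSE)
    utils::write.csv(report$concordance$breakdown,
                     file.path(config$out_dir, "concordance_breakdown.csv"), row.names = FALSE)
    imp_tbl <- purrr::imap(report$importance, function(ir, ap) {
      mutate(ir$importance, approach = ap, reduction = ir$reduction)
    }) %>% bind_rows()
    utils::write.csv(imp_tbl, file.path(config$out_dir, "importance.csv"), row.names = FALSE)
    summary_tbl <- tibble(key = c("concordance", "dmax_mtv_correlation", "prevalence"),
                          value = c(conc$concordance, dmax_mtv_r, mean(y)))
    utils::write.csv(summary_tbl, file.path(config$out_dir, "summary.csv"), row.names = FALSE)
  }
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>\n")
  cat(sprintf("  %d grid cells over %d approach(es)\n",
              nrow(x$grid), length(unique(x$grid$approach))))
  cat(sprintf("  largest==hottest concordance: %.2f\n", x$concordance$concordance))
  cat(sprintf("  Pearson r(Dmax_bulk, MTV): %.2f\n", x$dmax_mtv_correlation))
  print(x$best)
  invisible(x)
}
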