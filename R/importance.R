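#' Random-forest relative feature importance
#'
#' Fits a random forest on the features surviving the model
#' specification's reduction method (fitted on the full table) and returns impurity importances
#' normalized to sum to one. PCA specs are rejected: principal components
#' are not interpretable features. Preprocessing mirrors the CV pipeline
#' (log transform, z-scoring, and the specified oversampling choice).
#'
#' @param table A [build_feature_table()] result.
#' @param spec A [model_spec()] (or approach id); `reduction` must not be
#'   `"pca"`.
#' @param seed Seed for the oversampling draw and the forest.
#' @param num_trees Forest size (default 500).
#' @return An `importance_result` with a tibble of
#'   `(feature, importance)` pairs sorted decreasingly.
#' @export
feature_importance <- function(table, spec, seed = 1L, num_trees = 500L) {
  if (is.character(spec)) spec <- model_spec(spec)
  if (spec$reduction == "pca") {
    abort("feature importance is not computed for PCA-reduced models: principal components are not interpretable features")
  }
  y <- table$outcome
  X <- as.matrix(table[, setdiff(names(table), c("patient_id", "outcome")),
                       drop = FALSE])
  lt <- fit_log_transform(X)
  X <- apply_log_transform(X, lt)
  sc <- fit_scaler(X)
  X <- apply_scaler(X, sc)
  if (spec$oversampling == "interpolate") {
    sm <- oversample_smote(X, y, seed = seed)
    X <- sm$X; y <- sm$y
  }
  red <- withCallingHandlers(
    fit_reducer(spec$reduction, X, y, seed = seed, num_trees = num_trees),
    warning = function(w) invokeRestart("muffleWarning"))
  X <- predict_reducer(red, X)
  fit <- ranger::ranger(x = as.data.frame(X), y = factor(y),
                        num.trees = num_trees, importance = "impurity",
                        seed = seed, num.threads = 1)
  imp <- pmax(fit$variable.importance, 0)
  if (sum(imp) == 0) imp[] <- 1 / length(imp)
  imp <- imp / sum(imp)
  structure(list(
    importance = tibble(feature = names(imp), importance = as.numeric(imp)) %>%
      arrange(desc(.data$importance)),
    spec = spec, reduction = spec$reduction, num_trees = num_trees, seed = seed
  ), class = "importance_result")
}

#' @export
print.importance_result <- function(x, ...) {
  cat(sprintf("<importance_result> %s (reduction: %s), %d features\n",
              x$spec$approach, x$reduction, nrow(x$importance)))
  print(head(x$importance, 10))
  invisible(x)
}
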