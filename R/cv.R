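# Repeated stratified cross-validation of the ridge-logistic pipeline.

# outcome-stratified fold assignment: within each class, shuffled indices
# are dealt round-robin so fold sizes differ by at most one per class
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(sample.int(k), length(idx))
  }
  fold
}

#' Rank-based AUC
#'
#' Mann-Whitney AUC of `scores` against binary `labels`, with the usual 0.5
#' credit for ties.
#'
#' @param scores Numeric predictions (higher = more likely positive).
#' @param labels 0/1 outcomes, both classes present.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- as.numeric(sum(labels == 1)); n0 <- as.numeric(sum(labels == 0))
  if (n1 == 0 || n0 == 0) abort("AUC needs both classes")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# fit the within-fold pipeline and score test rows.
# Steps (training data only): skewness-gated log transform -> z-scoring ->
# optional SMOTE -> optional reduction -> ridge logistic regression with a
# fixed penalty strength of 1 in the mean-log-likelihood convention
# (glmnet lambda = 1/n_train).
fit_score_fold <- function(X_tr, y_tr, X_te, spec, fold_seed, num_trees = 500L,
                           lambda = NULL) {
  lt <- fit_log_transform(X_tr)
  X_tr <- apply_log_transform(X_tr, lt)
  X_te <- apply_log_transform(X_te, lt)
  sc <- fit_scaler(X_tr)
  X_tr <- apply_scaler(X_tr, sc)
  X_te <- apply_scaler(X_te, sc)
  if (spec$oversampling == "interpolate") {
    sm <- oversample_smote(X_tr, y_tr, k_neighbors = 5, seed = fold_seed)
    X_tr <- sm$X; y_tr <- sm$y
  }
  red <- withCallingHandlers(
    fit_reducer(spec$reduction, X_tr, y_tr, seed = fold_seed, num_trees = num_trees),
    warning = function(w) invokeRestart("muffleWarning"))
  X_tr <- predict_reducer(red, X_tr)
  X_te <- predict_reducer(red, X_te)
  if (ncol(X_tr) == 1L) {   # glmnet needs >= 2 columns
    X_tr <- cbind(X_tr, `..const` = 0)
    X_te <- cbind(X_te, `..const` = 0)
  }
  if (is.null(lambda)) lambda <- 1 / nrow(X_tr)
  fit <- withCallingHandlers(
    glmnet::glmnet(X_tr, y_tr, family = "binomial", alpha = 0,
                   lambda = lambda, standardize = FALSE),
    warning = function(w) invokeRestart("muffleWarning"))  # small-fold class-size notes
  drop(stats::predict(fit, newx = X_te, type = "response"))
}

#' Repeated stratified cross-validation of one model
#'
#' For each of `n_repeats` repeats, patients are split into `n_folds`
#' outcome-stratified folds; in each fold the preprocessing pipeline and a
#' ridge-penalized logistic regression are fitted on the training 80% and
#' the unseen 20% is scored, yielding one test-fold AUC. The mean and SD
#' are taken over all `n_repeats * n_folds` fold AUCs.
#'
#' @param table A [build_feature_table()] result (`patient_id`, `outcome`,
#'   features).
#' @param spec A [model_spec()] (or approach id).
#' @param n_folds,n_repeats CV geometry (defaults 5 x 50).
#' @param seed Master seed; per-repeat fold seeds and per-fold SMOTE /
#'   reducer seeds are derived from it.
#' @param folds Optional precomputed fold assignment (list of integer
#'   vectors, one per repeat) so that two models can share folds for paired
#'   comparison.
#' @param num_trees Random forest size inside `rfe_rf`.
#' @param lambda Ridge penalty of the logistic classifier; the default
#'   (`NULL`) uses unit penalty strength in the mean-log-likelihood
#'   convention, i.e. glmnet `lambda = 1/n_train`.
#' @return A `cv_result`: per-fold AUCs, mean and SD, the spec, seeds, fold
#'   assignments and per-fold test predictions.
#' @export
run_repeated_cv <- function(table, spec, n_folds = 5, n_repeats = 50,
                            seed = 1L, folds = NULL, num_trees = 500L,
                            lambda = NULL) {
  if (is.character(spec)) spec <- model_spec(spec)
  y <- table$outcome
  if (length(unique(y)) < 2) abort("outcome has a single class")
  if (min(table(y)) < n_folds) abort("each class needs at least n_folds members")
  X_all <- as.matrix(table[, setdiff(names(table), c("patient_id", "outcome")),
                           drop = FALSE])
  if (is.null(folds)) {
    folds <- lapply(seq_len(n_repeats),
                    function(r) stratified_folds(y, n_folds, derive_seed(seed, r)))
  }
  aucs <- list(); preds <- list()
  for (r in seq_len(n_repeats)) {
    fold <- folds[[r]]
    for (f in seq_len(n_folds)) {
      te <- which(fold == f); tr <- which(fold != f)
      if (length(unique(y[te])) < 2 || length(unique(y[tr])) < 2) {
        warn(sprintf("fold %d of repeat %d has a single class; skipped", f, r))
        next
      }
      fold_seed <- derive_seed(seed, r * 1000L + f)
      sc <- fit_score_fold(X_all[tr, , drop = FALSE], y[tr],
                           X_all[te, , drop = FALSE], spec, fold_seed,
                           num_trees = num_trees, lambda = lambda)
      aucs[[length(aucs) + 1]] <- tibble(repeat_ = r, fold = f,
                                         auc = auc_score(sc, y[te]),
                                         n_test = length(te))
      preds[[length(preds) + 1]] <- tibble(repeat_ = r, fold = f, row = te,
                                           score = sc, label = y[te])
    }
  }
  aucs <- bind_rows(aucs)
  structure(list(spec = spec, aucs = aucs,
                 mean_auc = mean(aucs$auc), sd_auc = sd(aucs$auc),
                 n_folds = n_folds, n_repeats = n_repeats, seed = seed,
                 folds = folds, predictions = bind_rows(preds)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s | %d x %d-fold CV | CV-AUC %.3f +/- %.3f\n",
              x$spec$approach, x$n_repeats, x$n_folds, x$mean_auc, x$sd_auc))
  invisible(x)
}
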