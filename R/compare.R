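#' DeLong test for two correlated AUCs
#'
#' Two-sided test of equality of the AUCs of two score vectors on the same
#' labeled cases, using DeLong's variance estimate based on paired
#' placement values. Identical (or perfectly concordant) scores give an
#' AUC difference of 0 and p = 1.
#'
#' @param scores_a,scores_b Numeric predictions on the same cases.
#' @param labels 0/1 outcomes; both classes must be present.
#' @return A list: `p`, `auc_a`, `auc_b`, `auc_diff`, `se`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.integer(labels)
  if (length(scores_a) != length(labels) || length(scores_b) != length(labels)) {
    abort("score vectors and labels must have equal length")
  }
  if (length(unique(labels)) < 2) abort("labels contain a single class")
  pos <- which(labels == 1); neg <- which(labels == 0)
  m <- length(pos); n <- length(neg)
  placements <- function(s) {
    # V10[i] = fraction of negatives each positive beats (ties = 1/2);
    # V01[j] likewise for negatives
    sp <- s[pos]; sn <- s[neg]
    v10 <- vapply(sp, function(x) (sum(x > sn) + 0.5 * sum(x == sn)) / n, numeric(1))
    v01 <- vapply(sn, function(x) (sum(sp > x) + 0.5 * sum(sp == x)) / m, numeric(1))
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  pa <- placements(scores_a)
  pb <- placements(scores_b)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  diff <- pa$auc - pb$auc
  if (!is.finite(var_diff)) {
    # a single positive or negative leaves the paired variance undefined:
    # no evidence either way
    return(list(p = 1, auc_a = pa$auc, auc_b = pb$auc, auc_diff = diff, se = NA_real_))
  }
  if (var_diff <= 1e-16) {
    p <- if (abs(diff) <= 1e-12) 1 else 0
    return(list(p = p, auc_a = pa$auc, auc_b = pb$auc, auc_diff = diff, se = 0))
  }
  z <- diff / sqrt(var_diff)
  list(p = 2 * stats::pnorm(-abs(z)), auc_a = pa$auc, auc_b = pb$auc,
       auc_diff = diff, se = sqrt(var_diff))
}

#' Compare two model specifications by fold-wise DeLong tests
#'
#' Builds the feature tables for both specs on the same patients, runs
#' repeated stratified CV with *shared* fold assignments, applies the
#' DeLong test to the paired test-fold predictions of every fold, and
#' reports the median of the fold p values as the final p value.
#'
#' @param features A [extract_cohort_features()] result.
#' @param spec_a,spec_b [model_spec()]s (or approach ids).
#' @param n_folds,n_repeats CV geometry.
#' @param seed Master seed (shared by both models).
#' @param num_trees Random forest size inside `rfe_rf`.
#' @return A `model_comparison`: per-fold p values, `median_p`, both
#'   `cv_result`s.
#' @export
compare_models <- function(features, spec_a, spec_b, n_folds = 5,
                           n_repeats = 50, seed = 1L, num_trees = 500L) {
  if (is.character(spec_a)) spec_a <- model_spec(spec_a)
  if (is.character(spec_b)) spec_b <- model_spec(spec_b)
  ta <- build_feature_table(features, spec_a)
  tb <- build_feature_table(features, spec_b)
  if (!identical(ta$patient_id, tb$patient_id)) abort("tables cover different patients")
  y <- ta$outcome
  folds <- lapply(seq_len(n_repeats),
                  function(r) stratified_folds(y, n_folds, derive_seed(seed, r)))
  cv_a <- run_repeated_cv(ta, spec_a, n_folds, n_repeats, seed, folds = folds,
                          num_trees = num_trees)
  cv_b <- run_repeated_cv(tb, spec_b, n_folds, n_repeats, seed, folds = folds,
                          num_trees = num_trees)
  compare_cv_results(cv_a, cv_b)
}

#' Fold-wise DeLong comparison of two finished CV runs
#'
#' Both runs must share fold assignments (as arranged by [compare_models()]).
#'
#' @param cv_a,cv_b `cv_result`s with stored predictions.
#' @return A `model_comparison`.
#' @export
compare_cv_results <- function(cv_a, cv_b) {
  if (!identical(cv_a$folds, cv_b$folds)) {
    abort("cv results were not run on shared fold assignments")
  }
  pa <- cv_a$predictions; pb <- cv_b$predictions
  key <- function(p) split(p, interaction(p$repeat_, p$fold, drop = TRUE))
  la <- key(pa); lb <- key(pb)
  stopifnot(identical(names(la), names(lb)))
  rows <- purrr::map2(la, lb, function(a, b) {
    stopifnot(identical(a$row, b$row))
    dl <- delong_test(a$score, b$score, a$label)
    tibble(repeat_ = a$repeat_[1], fold = a$fold[1], p = dl$p,
           auc_a = dl$auc_a, auc_b = dl$auc_b)
  })
  fold_p <- bind_rows(rows) %>% arrange(.data$repeat_, .data$fold)
  structure(list(spec_a = cv_a$spec, spec_b = cv_b$spec, fold_p = fold_p,
                 median_p = median(fold_p$p), cv_a = cv_a, cv_b = cv_b),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> %s (CV-AUC %.3f) vs %s (CV-AUC %.3f)\n",
              x$spec_a$approach, x$cv_a$mean_auc,
              x$spec_b$approach, x$cv_b$mean_auc))
  cat(sprintf("  median fold-wise DeLong p = %.4f over %d folds\n",
              x$median_p, nrow(x$fold_p)))
  invisible(x)
}
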