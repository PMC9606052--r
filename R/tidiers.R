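# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' Tidy a cross-validation result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return A tibble with one row per (repeat, fold): `repeat_`, `fold`,
#'   `auc`, `n_test`.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$aucs

#' One-row summary of a cross-validation result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return A tibble: approach, oversampling, reduction, mean and SD of the
#'   fold AUCs, fold counts.
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble(approach = x$spec$approach, oversampling = x$spec$oversampling,
         reduction = x$spec$reduction, mean_cv_auc = x$mean_auc,
         sd_cv_auc = x$sd_auc, n_folds = x$n_folds, n_repeats = x$n_repeats,
         n_fold_aucs = nrow(x$aucs))
}

#' @rdname tidy.cv_result
#' @method tidy model_comparison
#' @export
tidy.model_comparison <- function(x, ...) x$fold_p

#' @rdname glance.cv_result
#' @method glance model_comparison
#' @export
glance.model_comparison <- function(x, ...) {
  tibble(approach_a = x$spec_a$approach, approach_b = x$spec_b$approach,
         mean_cv_auc_a = x$cv_a$mean_auc, mean_cv_auc_b = x$cv_b$mean_auc,
         median_p = x$median_p, n_folds = nrow(x$fold_p))
}

#' @rdname tidy.cv_result
#' @method tidy importance_result
#' @export
tidy.importance_result <- function(x, ...) x$importance

#' Distribution of fold AUCs
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot object (boxplot of fold AUCs with the mean marked).
#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) {
  df <- object$aucs
  ggplot2::ggplot(df, ggplot2::aes(x = "", y = .data$auc)) +
    ggplot2::geom_boxplot(width = 0.3, outlier.alpha = 0.4) +
    ggplot2::geom_hline(yintercept = object$mean_auc, linetype = 2) +
    ggplot2::labs(x = NULL, y = "test-fold AUC",
                  title = sprintf("%s: CV-AUC %.2f +/- %.2f",
                                  object$spec$approach, object$mean_auc,
                                  object$sd_auc)) +
    ggplot2::theme_minimal()
}

#' Top feature importances
#'
#' @param object An `importance_result`.
#' @param top_n Number of features to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot importance_result
#' @export
autoplot.importance_result <- function(object, top_n = 20, ...) {
  df <- head(object$importance, top_n)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$importance, y = .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "relative importance", y = NULL,
                  title = sprintf("%s (reduction: %s)", object$spec$approach,
                                  object$reduction)) +
    ggplot2::theme_minimal()
}

#' Grid of mean CV-AUCs from an experiment report
#'
#' @param object An `experiment_report`.
#' @param ... Unused.
#' @return A ggplot object (tile grid approach x reduction, faceted by
#'   oversampling).
#' @method autoplot experiment_report
#' @export
autoplot.experiment_report <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = .data$reduction, y = .data$approach,
                               fill = .data$mean_cv_auc)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~oversampling) +
    ggplot2::scale_fill_viridis_c(name = "mean CV-AUC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
generics::tidy

#' @export
generics::glance
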