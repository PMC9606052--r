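# Preprocessing: skewness-gated log transform, z-scoring, SMOTE
# oversampling, and the six feature-reduction methods. Everything here has
# a fit/apply split so that, inside cross-validation, all decisions are
# made on training data only.

sample_skewness <- function(x) {
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (s == 0) 0 else mean((x - mu)^3) / s^3
}

# fit: which strictly positive columns have skewness > threshold
fit_log_transform <- function(X, skew_threshold = 0.5) {
  skew <- apply(X, 2, sample_skewness)
  pos <- apply(X, 2, function(x) all(x > 0))
  cols <- which(skew > skew_threshold & pos)
  floors <- if (length(cols)) apply(X[, cols, drop = FALSE], 2, min) else numeric(0)
  list(cols = cols, floors = floors, skew_threshold = skew_threshold)
}

apply_log_transform <- function(X, fit) {
  for (k in seq_along(fit$cols)) {
    j <- fit$cols[k]
    # unseen rows may contain values at or below 0; clip to half the
    # smallest training value so the log stays finite
    X[, j] <- log(pmax(X[, j], fit$floors[k] / 2))
  }
  X
}

#' Log-transform right-skewed feature columns
#'
#' Columns with sample skewness above `skew_threshold` (default 0.5) whose
#' values are strictly positive are replaced by their natural logarithm;
#' other columns are untouched. Inside cross-validation the same decision
#' is fitted on training folds only; this exported version operates on a
#' whole table for exploratory use.
#'
#' @param table A tibble; non-numeric columns and `patient_id` / `outcome`
#'   are passed through.
#' @param skew_threshold Skewness cut-off.
#' @return The transformed tibble, with attribute `"log_columns"` naming the
#'   transformed columns.
#' @export
log_transform_skewed <- function(table, skew_threshold = 0.5) {
  keep <- names(table) %in% c("patient_id", "outcome") |
    !vapply(table, is.numeric, logical(1))
  X <- as.matrix(table[, !keep, drop = FALSE])
  fit <- fit_log_transform(X, skew_threshold)
  X <- apply_log_transform(X, fit)
  table[, !keep] <- as_tibble(X)
  attr(table, "log_columns") <- colnames(X)[fit$cols]
  table
}

fit_scaler <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(mu = mu, sd = sdv)
}

apply_scaler <- function(X, fit) sweep(sweep(X, 2, fit$mu), 2, fit$sd, "/")

#' SMOTE oversampling of the minority class
#'
#' Balances the two classes by adding synthetic minority rows: each is a
#' convex combination of a random minority row and one of its `k_neighbors`
#' nearest minority neighbors (Euclidean distance). When the minority class
#' has fewer than `k_neighbors + 1` members, `k` is reduced accordingly.
#'
#' @param X Numeric matrix (rows = samples).
#' @param y Binary 0/1 vector.
#' @param k_neighbors Number of minority nearest neighbors, default 5.
#' @param seed Seed for the interpolation draws.
#' @return A list with the augmented `X` and `y`.
#' @export
oversample_smote <- function(X, y, k_neighbors = 5, seed = 1L) {
  y <- as.integer(y)
  tab <- table(factor(y, levels = c(0, 1)))
  if (any(tab == 0)) abort("SMOTE needs both classes present")
  minority <- as.integer(names(which.min(tab)))
  idx_min <- which(y == minority)
  n_new <- as.integer(max(tab) - min(tab))
  if (n_new == 0) return(list(X = X, y = y))
  if (length(idx_min) < 2) abort("minority class must have at least 2 members")
  k <- min(k_neighbors, length(idx_min) - 1)
  Xm <- X[idx_min, , drop = FALSE]
  D <- as.matrix(stats::dist(Xm))
  diag(D) <- Inf
  nbrs <- t(apply(D, 1, function(d) order(d)[seq_len(k)]))
  set.seed(seed)
  base <- sample(seq_along(idx_min), n_new, replace = TRUE)
  pick <- nbrs[cbind(base, sample(seq_len(k), n_new, replace = TRUE))]
  u <- runif(n_new)
  Xnew <- Xm[base, , drop = FALSE] + u * (Xm[pick, , drop = FALSE] - Xm[base, , drop = FALSE])
  list(X = rbind(X, Xnew), y = c(y, rep(minority, n_new)))
}

# ---- feature reduction -----------------------------------------------------

#' Fit a feature-reduction transformer on training data
#'
#' Methods: `"pca"` (components explaining 95% of training variance),
#' `"fa"` (principal-axis factor analysis, same component count as PCA),
#' `"rfe_rf"` / `"rfe_svm"` / `"rfe_lr"` (recursive feature elimination
#' dropping 10% per iteration down to 10 features, ranked by random-forest
#' impurity importance, linear-SVM weights, or ridge-logistic coefficient
#' magnitude), `"anova_top10pct"` (top 10th percentile by one-way ANOVA F
#' statistic) and `"none"`. Constant features are dropped with a warning
#' before fitting. The returned object transforms unseen rows via
#' [predict_reducer()].
#'
#' @param method Reduction method name.
#' @param X Numeric training matrix (assumed standardized).
#' @param y Binary outcome vector.
#' @param seed Seed for the stochastic rankers.
#' @param num_trees Random forest size for `rfe_rf`.
#' @return A `petrad_reducer` object.
#' @export
fit_reducer <- function(method, X, y, seed = 1L, num_trees = 500L) {
  method <- match.arg(method, c("none", "pca", "fa", "rfe_rf", "rfe_svm",
                                "rfe_lr", "anova_top10pct"))
  if (length(unique(y)) < 2) abort("training outcome has a single class")
  const <- apply(X, 2, function(x) max(x) - min(x) == 0)
  if (any(const)) {
    warn(sprintf("dropping %d constant feature(s) before reduction", sum(const)))
    X <- X[, !const, drop = FALSE]
  }
  keep_cols <- colnames(X)
  if (ncol(X) < 1) abort("no non-constant features left")
  obj <- switch(method,
    none = list(),
    pca = {
      pc <- prcomp(X, center = TRUE, scale. = FALSE)
      cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
      m <- which(cum >= 0.95)[1]
      list(rotation = pc$rotation[, seq_len(m), drop = FALSE], center = pc$center)
    },
    fa = {
      pc <- prcomp(X, center = TRUE, scale. = FALSE)
      cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
      m <- which(cum >= 0.95)[1]
      fa_fit_principal_axis(X, m)
    },
    rfe_rf = rfe_fit(X, y, rank_rf, seed = seed, num_trees = num_trees),
    rfe_svm = rfe_fit(X, y, rank_svm, seed = seed),
    rfe_lr = rfe_fit(X, y, rank_lr, seed = seed),
    anova_top10pct = {
      f <- apply(X, 2, function(x) anova_f(x, y))
      n_keep <- max(1L, ceiling(0.10 * ncol(X)))
      list(selected = colnames(X)[order(-f)[seq_len(n_keep)]])
    })
  structure(c(obj, list(method = method, keep_cols = keep_cols)),
            class = "petrad_reducer")
}

#' Apply a fitted reducer to new rows
#'
#' @param reducer A [fit_reducer()] result.
#' @param X Numeric matrix with the training columns.
#' @return The transformed matrix.
#' @export
predict_reducer <- function(reducer, X) {
  X <- X[, reducer$keep_cols, drop = FALSE]
  switch(reducer$method,
    none = X,
    pca = sweep(X, 2, reducer$center) %*% reducer$rotation,
    fa = {
      S <- sweep(X, 2, reducer$center) %*% reducer$scores_weights
      colnames(S) <- paste0("factor_", seq_len(ncol(S)))
      S
    },
    rfe_rf = , rfe_svm = , rfe_lr = , anova_top10pct =
      X[, reducer$selected, drop = FALSE])
}

# one-way ANOVA F statistic for a two-group comparison
anova_f <- function(x, y) {
  g <- split(x, y)
  if (length(g) < 2) return(0)
  n <- length(x); k <- length(g)
  mu <- mean(x)
  ssb <- sum(vapply(g, function(v) length(v) * (mean(v) - mu)^2, numeric(1)))
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1)))
  if (ssw == 0) return(Inf)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# principal-axis factor analysis: eigen decomposition of the correlation
# matrix with iterated communalities; factor scores by least squares on the
# loadings
fa_fit_principal_axis <- function(X, m, n_iter = 25L) {
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sdv <- apply(Xc, 2, sd); sdv[sdv == 0] <- 1
  Z <- sweep(Xc, 2, sdv, "/")
  R <- crossprod(Z) / (nrow(Z) - 1)
  h2 <- rep(0.5, ncol(R))
  for (it in seq_len(n_iter)) {
    Rh <- R; diag(Rh) <- h2
    ei <- eigen(Rh, symmetric = TRUE)
    vals <- pmax(ei$values[seq_len(m)], 0)
    L <- ei$vectors[, seq_len(m), drop = FALSE] %*% diag(sqrt(vals), m)
    h2_new <- pmin(rowSums(L^2), 1)
    if (max(abs(h2_new - h2)) < 1e-4) { h2 <- h2_new; break }
    h2 <- h2_new
  }
  Rh <- R; diag(Rh) <- h2
  ei <- eigen(Rh, symmetric = TRUE)
  vals <- pmax(ei$values[seq_len(m)], 0)
  L <- ei$vectors[, seq_len(m), drop = FALSE] %*% diag(sqrt(vals), m)
  # scores: Z %*% L (L'L)^-1, absorbing the 1/sd scaling into the weights
  W <- L %*% solve(crossprod(L) + diag(1e-8, m))
  weights <- sweep(W, 1, sdv, "/")
  list(center = ctr, loadings = L, scores_weights = weights)
}

# ---- recursive feature elimination ----------------------------------------

rfe_fit <- function(X, y, ranker, seed = 1L, target = 10L, drop_frac = 0.10, ...) {
  cols <- colnames(X)
  it <- 0L
  while (length(cols) > target) {
    it <- it + 1L
    r <- ranker(X[, cols, drop = FALSE], y, seed = seed + it, ...)
    n_drop <- min(max(1L, floor(drop_frac * length(cols))), length(cols) - target)
    cols <- cols[order(-r)][seq_len(length(cols) - n_drop)]
  }
  list(selected = cols)
}

rank_rf <- function(X, y, seed = 1L, num_trees = 500L) {
  fit <- ranger::ranger(x = as.data.frame(X), y = factor(y),
                        num.trees = num_trees, importance = "impurity",
                        seed = seed, num.threads = 1)
  imp <- fit$variable.importance
  imp[colnames(X)]
}

rank_svm <- function(X, y, seed = 1L) {
  fit <- e1071::svm(x = X, y = factor(y), kernel = "linear", scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  abs(w)[colnames(X)]
}

rank_lr <- function(X, y, seed = 1L) {
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                        lambda = 1 / nrow(X), standardize = FALSE)
  b <- abs(as.numeric(stats::coef(fit))[-1])
  setNames(b, colnames(X))[colnames(X)]
}
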