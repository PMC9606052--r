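# log transform, SMOTE and feature reduction

test_that("log transform targets skewed, strictly positive columns only", {
  set.seed(2)
  n <- 10000
  tbl <- tibble::tibble(
    patient_id = 1:n, outcome = rep_len(0:1, n),
    symmetric = rnorm(n),
    lognormal = exp(rnorm(n)),
    skewed_with_zero = c(0, exp(rnorm(n - 1)))
  )
  out <- log_transform_skewed(tbl)
  expect_equal(attr(out, "log_columns"), "lognormal")
  expect_equal(out$symmetric, tbl$symmetric)
  expect_equal(out$skewed_with_zero, tbl$skewed_with_zero)   # positivity rule
  expect_equal(out$lognormal, log(tbl$lognormal))
  # post-transform skewness near zero for the lognormal column
  expect_lt(abs(petrad:::sample_skewness(out$lognormal)), 0.1)
})

test_that("fitted log transform clips unseen non-positive values", {
  Xtr <- cbind(f = exp(rnorm(500, 0, 1)) + 0.5)
  fit <- petrad:::fit_log_transform(Xtr)
  Xte <- cbind(f = c(-1, 0, 2))
  out <- petrad:::apply_log_transform(Xte, fit)
  expect_true(all(is.finite(out)))
})

test_that("SMOTE balances classes by convex interpolation", {
  set.seed(3)
  X <- matrix(rnorm(50 * 4), 50, 4)
  y <- c(rep(1, 10), rep(0, 40))
  out <- oversample_smote(X, y, seed = 5)
  expect_equal(sum(out$y == 1), 40)
  expect_equal(sum(out$y == 0), 40)
  # identical minority points produce identical synthetic points
  X2 <- X; X2[1:10, ] <- matrix(rep(c(1, 2, 3, 4), each = 10), 10, 4)
  out2 <- oversample_smote(X2, y, seed = 5)
  syn <- out2$X[-(1:50), , drop = FALSE]
  expect_true(all(abs(sweep(syn, 2, c(1, 2, 3, 4))) < 1e-12))
  # minority on a segment stays on the segment
  X3 <- X
  tpar <- seq(0, 1, length.out = 10)
  X3[1:10, ] <- outer(tpar, c(2, -1, 0, 3))
  out3 <- oversample_smote(X3, y, seed = 7)
  syn3 <- out3$X[-(1:50), , drop = FALSE]
  # each synthetic row is proportional to the direction vector
  coefs <- syn3 %*% c(2, -1, 0, 3) / sum(c(2, -1, 0, 3)^2)
  expect_equal(syn3, outer(drop(coefs), c(2, -1, 0, 3)), tolerance = 1e-9)
  expect_error(oversample_smote(X, rep(1, 50)), "both classes")
})

test_that("ANOVA selection keeps the top 10th percentile", {
  set.seed(4)
  n <- 60
  X <- matrix(rnorm(n * 480), n, 480,
              dimnames = list(NULL, paste0("f", 1:480)))
  y <- rep(0:1, each = 30)
  X[, 7] <- X[, 7] + y * 3
  red <- fit_reducer("anova_top10pct", X, y)
  expect_length(red$selected, 48)
  expect_true("f7" %in% red$selected)
  expect_equal(dim(predict_reducer(red, X)), c(n, 48))
})

test_that("PCA on two orthogonal informative directions keeps all variance", {
  set.seed(5)
  n <- 100
  basis <- qr.Q(qr(matrix(rnorm(4), 2, 2)))
  scores <- matrix(rnorm(n * 2), n, 2)
  X <- scores %*% t(basis)
  colnames(X) <- c("a", "b")
  y <- rep(0:1, each = 50)
  red <- fit_reducer("pca", X, y)
  Z <- predict_reducer(red, X)
  # reconstruction from retained components is exact
  Xhat <- Z %*% t(red$rotation)
  Xhat <- sweep(Xhat, 2, -red$center)
  expect_equal(unname(Xhat), unname(X), tolerance = 1e-9)
})

test_that("factor analysis produces usable scores on unseen rows", {
  set.seed(6)
  n <- 80
  f <- rnorm(n)
  X <- cbind(a = f + rnorm(n, 0, 0.3), b = -f + rnorm(n, 0, 0.3),
             c = 2 * f + rnorm(n, 0, 0.3), d = rnorm(n))
  y <- as.integer(f > 0)
  red <- fit_reducer("fa", X, y)
  Znew <- predict_reducer(red, X[1:5, , drop = FALSE])
  expect_equal(nrow(Znew), 5)
  expect_true(all(is.finite(Znew)))
  # the dominant factor tracks the latent variable
  Z <- predict_reducer(red, X)
  expect_gt(abs(cor(Z[, 1], f)), 0.9)
})

test_that("RFE variants reduce to 10 features and keep the informative one", {
  set.seed(7)
  n <- 80
  X <- matrix(rnorm(n * 25), n, 25, dimnames = list(NULL, paste0("f", 1:25)))
  y <- as.integer(X[, 13] + rnorm(n, 0, 0.4) > 0)
  for (m in c("rfe_svm", "rfe_lr")) {
    red <- fit_reducer(m, X, y, seed = 1)
    expect_length(red$selected, 10)
    expect_true("f13" %in% red$selected)
  }
})

test_that("random-forest RFE ranks a single determining feature first", {
  hits <- vapply(1:40, function(s) {
    set.seed(s)
    n <- 60
    X <- matrix(rnorm(n * 11), n, 11, dimnames = list(NULL, paste0("f", 1:11)))
    y <- as.integer(X[, 4] > 0)
    r <- petrad:::rank_rf(X, y, seed = s, num_trees = 200)
    names(which.max(r)) == "f4"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("constant features are dropped with a warning before fitting", {
  set.seed(8)
  X <- cbind(a = rnorm(40), b = rep(2, 40), c = rnorm(40))
  y <- rep(0:1, 20)
  expect_warning(red <- fit_reducer("anova_top10pct", X, y), "constant")
  expect_false("b" %in% red$keep_cols)
})
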