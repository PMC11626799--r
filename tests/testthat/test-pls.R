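test_that("an exact single-direction relationship is fit with 1 LV", {
  set.seed(10)
  x <- rnorm(20)
  X <- cbind(x, 3 * x - 1, -0.5 * x)        # rank-1 predictor block
  y <- 2 * x + 5
  fit <- fit_pls(X, y, n_lv = 1, scale = FALSE)
  st <- fit_statistics(y, predict(fit, X))
  expect_gt(st$r2, 1 - 1e-10)
  expect_lt(st$rmse, 1e-8)
})

test_that("full-rank PLS equals ordinary least squares", {
  set.seed(11)
  n <- 30; p <- 5
  X <- matrix(rnorm(n * p), n, p)
  y <- X %*% runif(p) + rnorm(n)
  fit <- fit_pls(X, y, n_lv = p)
  cf <- pls_coefficients(fit)
  ols <- lm.fit(cbind(1, X), y)$coefficients
  expect_equal(cf$coef, unname(ols[-1]), tolerance = 1e-8)
  expect_equal(cf$intercept, unname(ols[1]), tolerance = 1e-8)
})

test_that("NIPALS agrees with the Krylov-subspace oracle at a < rank", {
  set.seed(12)
  n <- 25; p <- 8
  X <- matrix(rnorm(n * p), n, p)
  y <- X %*% runif(p) + rnorm(n, sd = 0.3)
  Xnew <- matrix(rnorm(5 * p), 5, p)
  for (a in c(1, 2, 4)) {
    fit <- fit_pls(X, y, n_lv = a)
    expect_equal(predict(fit, Xnew),
                 oracle_pls_predict(X, y, Xnew, a),
                 tolerance = 1e-8)
  }
})

test_that("sample order does not change the model", {
  set.seed(13)
  X <- matrix(rnorm(60), 15)
  y <- rnorm(15)
  perm <- sample(15)
  c1 <- pls_coefficients(fit_pls(X, y, 3))
  c2 <- pls_coefficients(fit_pls(X[perm, ], y[perm], 3))
  expect_equal(c1$coef, c2$coef, tolerance = 1e-12)
})

test_that("scores are orthogonal and training predictions reconstruct", {
  set.seed(14)
  X <- matrix(rnorm(40 * 10), 40)
  y <- rnorm(40)
  fit <- fit_pls(X, y, n_lv = 6)
  G <- crossprod(fit$Tt)
  offdiag <- G - diag(diag(G))
  expect_lt(max(abs(offdiag)) / max(diag(G)), 1e-8)
  # coefficient path reproduces the deflation-based fitted values
  fitted_scores <- as.numeric(fit$Tt %*% fit$q) + fit$y_center
  expect_equal(predict(fit, X), fitted_scores, tolerance = 1e-10)
})

test_that("training RMSE is non-increasing in the number of components", {
  set.seed(15)
  X <- matrix(rnorm(35 * 12), 35)
  y <- rnorm(35)
  fit <- fit_pls(X, y, n_lv = 10)
  rmse <- vapply(seq_len(fit$n_lv), function(a)
    sqrt(mean((y - predict(fit, X, a = a))^2)), numeric(1))
  expect_true(all(diff(rmse) <= 1e-12))
})

test_that("scaling the response scales RMSE and leaves R2 unchanged", {
  set.seed(16)
  X <- matrix(rnorm(60), 20)
  y <- X[, 1] + rnorm(20, sd = 0.5)
  f1 <- fit_pls(X, y, 2); f2 <- fit_pls(X, 7 * y, 2)
  s1 <- fit_statistics(y, predict(f1, X))
  s2 <- fit_statistics(7 * y, predict(f2, X))
  expect_equal(s2$rmse, 7 * s1$rmse, tolerance = 1e-10)
  expect_equal(s2$r2, s1$r2, tolerance = 1e-10)
})

test_that("zero-variance column is rejected when scaling", {
  X <- cbind(rnorm(10), 1)
  expect_error(fit_pls(X, rnorm(10), 1, scale = TRUE), "zero-variance")
  expect_silent(fit_pls(X, rnorm(10), 1, scale = FALSE))
})

test_that("LOO-CV predictions equal the held-out oracle refits", {
  set.seed(17)
  n <- 12; p <- 4
  X <- matrix(rnorm(n * p), n, p)
  y <- X %*% runif(p) + rnorm(n, sd = 0.2)
  cv <- loo_cv(X, y, max_lv = 3)
  for (i in seq_len(n)) for (a in 1:3) {
    expect_equal(cv$pred[i, a],
                 oracle_pls_predict(X[-i, ], y[-i],
                                    X[i, , drop = FALSE], a),
                 tolerance = 1e-8)
  }
})

test_that("noiseless low-rank problems choose few components", {
  set.seed(18)
  n <- 30
  basis <- matrix(rnorm(n * 2), n, 2)
  X <- basis %*% matrix(rnorm(2 * 10), 2, 10)
  y <- basis %*% c(1, -2)
  cv <- loo_cv(X, y + 0, max_lv = 6, scale = FALSE)
  expect_lte(cv$chosen_a, 2)
})

test_that("constant response is reported as r2 = 0 with a warning", {
  set.seed(19)
  X <- matrix(rnorm(30), 10)
  expect_warning(cv <- loo_cv(X, rep(2, 10), max_lv = 2), "constant")
  expect_equal(cv$r2_cv, c(0, 0))
})

test_that("residual-outlier filtering removes exactly the planted sample", {
  set.seed(20)
  n <- 25
  X <- matrix(rnorm(n * 3), n, 3)
  y <- as.numeric(X %*% c(1, 2, -1)) + rnorm(n, sd = 0.1)
  y[9] <- y[9] + 10 * 0.1 * 12          # far beyond 3 standardized residuals
  ro <- remove_residual_outliers(X, y, max_lv = 3)
  expect_identical(which(!ro$keep), 9L)
  expect_equal(ro$pct_removed, 100 / n)

  clean <- remove_residual_outliers(X, as.numeric(X %*% c(1, 2, -1)) +
                                      rnorm(n, sd = 0.1), max_lv = 3)
  expect_equal(clean$pct_removed, 0)

  inf <- remove_residual_outliers(X, y, max_lv = 3, sd_threshold = Inf)
  expect_true(all(inf$keep))
})

test_that("fit statistics match their closed forms", {
  y <- c(3, 1, 4, 1, 5)
  expect_equal(fit_statistics(y, y), list(r2 = 1, rmse = 0))
  st <- suppressWarnings(fit_statistics(y, rep(mean(y), 5)))
  expect_equal(st$rmse, sqrt(mean((y - mean(y))^2)))
  p <- c(2.5, 1.5, 3.5, 0.5, 5.5)
  st2 <- fit_statistics(y, p)
  expect_equal(st2$r2, cor(y, p)^2)
  expect_equal(st2$rmse, sqrt(mean((y - p)^2)))
  expect_error(fit_statistics(rep(1, 5), p), "constant")
})

test_that("R2 interpretation bands honour the printed boundaries", {
  expect_equal(classify_r2_band(0.91), "punctual")
  expect_equal(classify_r2_band(0.89), "quantitative_screening")
  expect_equal(classify_r2_band(0.82), "quantitative_screening")
  expect_equal(classify_r2_band(0.81), "approximate_screening")
  expect_equal(classify_r2_band(0.66), "approximate_screening")
  expect_equal(classify_r2_band(0.65), "extreme_detection")
  expect_equal(classify_r2_band(0.50), "extreme_detection")
  expect_equal(classify_r2_band(0.49), "insufficient")
  expect_equal(classify_r2_band(1), "punctual")
  expect_equal(classify_r2_band(0), "insufficient")
})
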