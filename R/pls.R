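#' Partial least squares regression by NIPALS
#'
#' Fits a univariate-response PLS model with component-wise deflation.
#' Predictors are optionally centered and scaled (sample SD, n-1 denominator)
#' with statistics stored in the model so new samples are projected exactly
#' as the training data were. Components are extracted until `n_lv` is
#' reached or the residual predictor-response covariance vanishes.
#'
#' @param X numeric predictor matrix, samples in rows; no missing values.
#' @param y numeric response vector.
#' @param n_lv number of latent variables to extract (1 <= n_lv < n).
#' @param center,scale center and/or scale the columns of `X` (and `y`,
#'   centered only) before extraction. Defaults mirror the usual
#'   chemometrics workflow: both on.
#' @return An object of class `pls_model` with the weight matrix `W`,
#'   loadings `P`, response loadings `q`, scores `Tt`, centering/scaling
#'   vectors, and `n_lv` the number of components actually extracted.
#' @seealso [predict.pls_model()], [pls_coefficients()], [loo_cv()]
#' @export
fit_pls <- function(X, y, n_lv, center = TRUE, scale = TRUE) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed")
  if (n_lv < 1 || n_lv >= n) stop("need n_samples > n_lv >= 1")
  x_center <- if (center) colMeans(X) else rep(0, p)
  x_scale <- if (scale) apply(X, 2, stats::sd) else rep(1, p)
  if (scale && any(x_scale == 0))
    stop("zero-variance predictor column(s): ",
         paste(utils::head(which(x_scale == 0), 5), collapse = ", "))
  y_center <- if (center) mean(y) else 0
  E <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  f <- y - y_center

  W <- P <- matrix(0, p, n_lv)
  Tt <- matrix(0, n, n_lv)
  q <- numeric(n_lv)
  a_used <- 0
  for (a in seq_len(n_lv)) {
    w <- crossprod(E, f)                       # p x 1, PLS1: no inner iteration
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) break                      # residual covariance exhausted
    w <- w / wn
    t <- E %*% w
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pv <- crossprod(E, t) / tt
    qa <- sum(f * t) / tt
    E <- E - tcrossprod(t, pv)
    f <- f - qa * t
    W[, a] <- w; P[, a] <- pv; Tt[, a] <- t; q[a] <- qa
    a_used <- a
  }
  if (a_used == 0) stop("no latent variable could be extracted (constant y?)")
  keep <- seq_len(a_used)
  structure(
    list(W = W[, keep, drop = FALSE], P = P[, keep, drop = FALSE],
         Tt = Tt[, keep, drop = FALSE], q = q[keep], n_lv = a_used,
         x_center = x_center, x_scale = x_scale, y_center = y_center),
    class = "pls_model")
}

#' Regression coefficients of a PLS model
#'
#' Returns the coefficient vector (on the original predictor scale) and
#' intercept implied by the first `a` latent variables:
#' `B = W (P'W)^-1 q`, unscaled column-wise.
#'
#' @param model a `pls_model`.
#' @param a number of components to use (default: all extracted).
#' @return List with `coef` (length p) and `intercept`.
#' @export
pls_coefficients <- function(model, a = model$n_lv) {
  stopifnot(inherits(model, "pls_model"), a >= 1, a <= model$n_lv)
  idx <- seq_len(a)
  Wa <- model$W[, idx, drop = FALSE]
  Pa <- model$P[, idx, drop = FALSE]
  B <- Wa %*% solve(crossprod(Pa, Wa), model$q[idx])
  coef <- as.numeric(B) / model$x_scale
  intercept <- model$y_center - sum(model$x_center * coef)
  list(coef = coef, intercept = intercept)
}

#' Predict from a fitted PLS model
#'
#' @param object a `pls_model`.
#' @param newdata numeric matrix of new samples (columns as in training).
#' @param a number of components to use (default: all extracted).
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, a = object$n_lv, ...) {
  newdata <- as.matrix(newdata)
  cf <- pls_coefficients(object, a)
  as.numeric(newdata %*% cf$coef + cf$intercept)
}

#' Goodness-of-fit statistics
#'
#' R-squared is the squared Pearson correlation of observed and predicted
#' values (the cross-validation convention of the standard chemometrics
#' workflow; the 1 - SSE/SST variant can be computed from the residuals);
#' RMSE uses the n denominator.
#'
#' @param observed,predicted numeric vectors of equal length >= 2; the
#'   observed values must not be constant.
#' @return List with `r2` and `rmse`.
#' @export
fit_statistics <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2)
    stop("observed and predicted must have equal length >= 2")
  if (stats::sd(observed) == 0) stop("observed values are constant")
  r <- stats::cor(observed, predicted)
  if (is.na(r)) r <- 0                        # constant predictions
  list(r2 = r^2, rmse = sqrt(mean((observed - predicted)^2)))
}

#' Leave-one-out cross-validation of a PLS model
#'
#' Each sample is predicted with components 1..`max_lv` from a model fitted
#' on the remaining n-1 samples; centering and scaling are recomputed inside
#' each fold so the held-out sample never leaks into the fit. The number of
#' components is chosen as the minimizer of the cross-validated RMSE, ties
#' broken toward fewer components.
#'
#' @param X predictor matrix; `y` response vector; n >= 3.
#' @param max_lv cap on the number of latent variables (default 20, and
#'   always < n-1).
#' @param center,scale passed to [fit_pls()].
#' @return List with `rmse_cv` and `r2_cv` (per component count),
#'   `chosen_a`, and the n x max_lv matrix `pred` of held-out predictions.
#' @export
loo_cv <- function(X, y, max_lv = 20, center = TRUE, scale = TRUE) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 samples")
  max_lv <- min(max_lv, ncol(X))
  if (max_lv >= n - 1) stop("max_lv must be < n - 1")
  if (stats::sd(y) == 0) {
    warning("constant response: r2_cv undefined, reported as 0")
    pred <- matrix(y[1], n, max_lv)
    return(list(rmse_cv = rep(0, max_lv), r2_cv = rep(0, max_lv),
                chosen_a = 1L, pred = pred))
  }
  pred <- matrix(NA_real_, n, max_lv)
  for (i in seq_len(n)) {
    fit <- fit_pls(X[-i, , drop = FALSE], y[-i], n_lv = max_lv,
                   center = center, scale = scale)
    for (a in seq_len(max_lv))
      pred[i, a] <- predict(fit, X[i, , drop = FALSE],
                            a = min(a, fit$n_lv))
  }
  rmse_cv <- sqrt(colMeans((pred - y)^2))
  if (stats::sd(y) == 0) {
    warning("constant response: r2_cv undefined, reported as 0")
    r2_cv <- rep(0, max_lv)
  } else {
    r2_cv <- apply(pred, 2, function(p) {
      r <- stats::cor(y, p); if (is.na(r)) 0 else r^2
    })
  }
  chosen_a <- which.min(rmse_cv)              # which.min takes the first tie
  list(rmse_cv = rmse_cv, r2_cv = r2_cv, chosen_a = chosen_a, pred = pred)
}

#' Drop samples with extreme cross-validated residuals
#'
#' One pass: leave-one-out residuals at the cross-validation-chosen
#' component count are standardized, and samples exceeding `sd_threshold`
#' are removed. No refit-and-repeat iteration.
#'
#' @param X predictor matrix; `y` response vector.
#' @param max_lv,center,scale settings forwarded to [loo_cv()].
#' @param sd_threshold standardized-residual cutoff (default 3).
#' @return List with `keep` (logical per sample), `pct_removed`, `chosen_a`
#'   and the standardized residuals `z`.
#' @export
remove_residual_outliers <- function(X, y, max_lv = 20, sd_threshold = 3,
                                     center = TRUE, scale = TRUE) {
  cv <- loo_cv(X, y, max_lv = max_lv, center = center, scale = scale)
  res <- y - cv$pred[, cv$chosen_a]
  s <- stats::sd(res)
  z <- if (s == 0) rep(0, length(res)) else (res - mean(res)) / s
  keep <- abs(z) <= sd_threshold
  if (sum(keep) < max_lv + 2)
    stop("removal would leave fewer than max_lv + 2 samples")
  list(keep = keep, pct_removed = 100 * mean(!keep), chosen_a = cv$chosen_a,
       z = z)
}

#' Interpretation band for a prediction R-squared
#'
#' The conventional chemometrics banding of model quality: R2 >= 0.91
#' supports punctual (per-sample) prediction; 0.82-0.90 good quantitative
#' screening; 0.66-0.81 approximate screening; 0.50-0.65 detection of
#' extreme values or group comparison only; below 0.50 the model is
#' insufficient. Band edges are closed at their printed two-decimal
#' boundaries; values in the unprinted gaps (e.g. 0.905) fall in the band
#' below the next closed lower edge.
#'
#' @param r2 a single R-squared in `[0, 1]`.
#' @return One of `"punctual"`, `"quantitative_screening"`,
#'   `"approximate_screening"`, `"extreme_detection"`, `"insufficient"`.
#' @export
classify_r2_band <- function(r2) {
  stopifnot(length(r2) == 1, !is.na(r2), r2 >= 0, r2 <= 1)
  if (r2 >= 0.91) "punctual"
  else if (r2 >= 0.82) "quantitative_screening"
  else if (r2 >= 0.66) "approximate_screening"
  else if (r2 >= 0.50) "extreme_detection"
  else "insufficient"
}
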