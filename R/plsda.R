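#' Published at-risk thresholds for blood traits
#'
#' Cut-offs above which a cow is considered at risk: blood BHB > 1.2 mmol/L
#' (subclinical ketosis), NEFA > 0.7 mmol/L (excessive fat mobilization /
#' negative energy balance), total bilirubin (BILT) > 4 umol/L.
#'
#' @return Data frame with columns `trait`, `cutoff`, `units`.
#' @export
default_risk_thresholds <- function() {
  data.frame(trait = c("blood_bhb", "blood_nefa", "blood_bilt"),
             cutoff = c(1.2, 0.7, 4),
             units = c("mmol/L", "mmol/L", "umol/L"),
             stringsAsFactors = FALSE)
}

#' Binary at-risk labels from a trait threshold
#'
#' Label 1 (at risk) iff the value is strictly above the cutoff; values
#' equal to the cutoff are not at risk.
#'
#' @param values numeric trait vector, no missing values.
#' @param cutoff positive threshold in the trait's units.
#' @return List with integer `labels` (0/1) and `prevalence_pct`. An
#'   all-one-class outcome triggers a warning (a downstream discriminant
#'   model would be untrainable).
#' @export
label_by_threshold <- function(values, cutoff) {
  if (anyNA(values)) stop("missing values are not allowed")
  stopifnot(cutoff > 0)
  labels <- as.integer(values > cutoff)
  if (length(unique(labels)) == 1)
    warning("all samples fall in one class (prevalence ",
            100 * mean(labels), "%)")
  list(labels = labels, prevalence_pct = 100 * mean(labels))
}

#' PLS discriminant analysis for a binary at-risk label
#'
#' The standard two-class construction: PLS1 regression on the 0/1 class
#' indicator, predicted class 1 iff the predicted score exceeds 0.5. The
#' component count is chosen by leave-one-out balanced accuracy (not RMSE
#' -- the objective is classification), ties broken toward fewer
#' components.
#'
#' @param X preprocessed spectra matrix (retained columns).
#' @param labels integer 0/1 vector; both classes must be present.
#' @param max_lv latent-variable cap (default 20).
#' @return A `plsda_model`: the underlying `pls_model`, `chosen_a`, the
#'   per-component LOO balanced accuracies `ba_cv`, and `cutoff = 0.5`.
#' @export
fit_plsda <- function(X, labels, max_lv = 20) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("both classes must be present in the training data")
  mlv <- min(max_lv, nrow(X) - 2, ncol(X))
  cv <- loo_cv(X, labels, max_lv = mlv)
  ba_cv <- apply(cv$pred, 2, function(p) {
    m <- classification_metrics(labels, as.integer(p > 0.5))
    if (is.na(m$balanced_accuracy)) 0 else m$balanced_accuracy
  })
  chosen_a <- which.max(ba_cv)               # first maximum = fewest LV
  fit <- fit_pls(X, labels, n_lv = chosen_a)
  structure(list(fit = fit, chosen_a = chosen_a, ba_cv = ba_cv,
                 cutoff = 0.5),
            class = "plsda_model")
}

#' @export
predict.plsda_model <- function(object, newdata, ...) {
  score <- predict(object$fit, newdata, a = object$chosen_a)
  as.integer(score > object$cutoff)
}

#' Confusion-matrix metrics for a binary classifier
#'
#' Sensitivity (true-positive rate), specificity (true-negative rate),
#' positive and negative predictive values, and balanced accuracy — the
#' exact mean of sensitivity and specificity. Ratios with a zero
#' denominator are reported as `NA`, never as 0. Rounding happens only at
#' report time via [round_half_up()].
#'
#' @param true,predicted integer 0/1 vectors of equal length.
#' @return A `classification_report` list with the five metrics and the
#'   confusion counts `tp`, `fp`, `tn`, `fn`.
#' @export
classification_metrics <- function(true, predicted) {
  if (length(true) != length(predicted))
    stop("true and predicted must have equal length")
  true <- as.integer(true); predicted <- as.integer(predicted)
  tp <- sum(true == 1 & predicted == 1)
  fp <- sum(true == 0 & predicted == 1)
  tn <- sum(true == 0 & predicted == 0)
  fn <- sum(true == 1 & predicted == 0)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  se <- ratio(tp, tp + fn)
  sp <- ratio(tn, tn + fp)
  structure(
    list(sensitivity = se, specificity = sp,
         ppv = ratio(tp, tp + fp), npv = ratio(tn, tn + fn),
         balanced_accuracy = (se + sp) / 2,
         tp = tp, fp = fp, tn = tn, fn = fn),
    class = "classification_report")
}

#' Round half away from zero
#'
#' Report-time rounding for classification metrics: exact halves round away
#' from zero (0.665 -> 0.67 at 2 digits), unlike base R's round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 2).
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' @export
print.classification_report <- function(x, ...) {
  f <- function(v) ifelse(is.na(v), "NA", format(round_half_up(v, 2)))
  cat("sensitivity ", f(x$sensitivity), "  specificity ", f(x$specificity),
      "  balanced accuracy ", f(x$balanced_accuracy), "\n", sep = "")
  cat("PPV ", f(x$ppv), "  NPV ", f(x$npv),
      "  (TP ", x$tp, ", FP ", x$fp, ", TN ", x$tn, ", FN ", x$fn, ")\n",
      sep = "")
  invisible(x)
}
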