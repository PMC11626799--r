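#' Stratified calibration/validation split with moment matching
#'
#' Draws random 70/30 (by default) splits within herd x parity x DIM-class
#' strata until calibration and validation sets have similar mean and SD of
#' the target trait: both |mean_cal - mean_val| and |sd_cal - sd_val| must
#' be at most `tolerance` times the overall trait SD. Candidate draws are
#' repeated up to `max_tries`; if none satisfies the constraints the best
#' candidate is returned with a warning. Allocation uses largest-remainder
#' rounding so the calibration fraction is exact to within one sample, and
#' every stratum with >= 2 members contributes at least one sample to each
#' set. Single-member strata go wholly to calibration (with a warning),
#' never dropped.
#'
#' @param records data frame with columns `cow_id`, `herd_id`,
#'   `parity_class`, `dim_class` and the target trait.
#' @param trait name of the trait column; rows with a missing value are
#'   excluded from the split.
#' @param frac calibration fraction (default 0.7).
#' @param seed integer seed; the split is deterministic given the seed.
#' @param max_tries candidate draws before falling back (default 200).
#' @param tolerance moment-matching tolerance as a multiple of the overall
#'   trait SD (default 0.1).
#' @return A `split_plan`: list with `calibration_ids`, `validation_ids`,
#'   `seed`, `accepted`, `tries`, and the achieved `stats`.
#' @export
stratified_split <- function(records, trait, frac = 0.7, seed = 1,
                             max_tries = 200, tolerance = 0.1) {
  stopifnot(is.data.frame(records),
            all(c("cow_id", "herd_id", "parity_class", "dim_class") %in%
                  names(records)),
            trait %in% names(records))
  rec <- records[!is.na(records[[trait]]), , drop = FALSE]
  n <- nrow(rec)
  if (n < 10) stop("need at least 10 samples with a non-missing trait value")
  y <- rec[[trait]]
  sd_all <- stats::sd(y)
  strata <- interaction(rec$herd_id, rec$parity_class, rec$dim_class,
                        drop = TRUE)
  sizes <- table(strata)
  if (any(sizes == 1))
    warning(sum(sizes == 1),
            " single-member stratum/strata assigned wholly to calibration")

  # largest-remainder allocation of the calibration count across strata
  target <- round(frac * n)
  lev <- names(sizes)
  n_s <- as.integer(sizes)
  alloc <- ifelse(n_s == 1, 1L, pmax(1L, floor(frac * n_s)))
  alloc <- pmin(alloc, pmax(1L, n_s - ifelse(n_s >= 2, 1L, 0L)))
  room_up <- ifelse(n_s >= 2, (n_s - 1L) - alloc, 0L)
  room_dn <- ifelse(n_s >= 2, alloc - 1L, 0L)
  fracpart <- frac * n_s - floor(frac * n_s)
  deficit <- target - sum(alloc)
  if (deficit > 0) {
    o <- order(-fracpart)
    for (j in o) {
      if (deficit == 0) break
      add <- min(room_up[j], deficit)
      alloc[j] <- alloc[j] + add; deficit <- deficit - add
    }
  } else if (deficit < 0) {
    o <- order(fracpart)
    for (j in o) {
      if (deficit == 0) break
      sub <- min(room_dn[j], -deficit)
      alloc[j] <- alloc[j] - sub; deficit <- deficit + sub
    }
  }

  set.seed(seed)
  best <- NULL; best_score <- Inf; accepted <- FALSE; tries <- 0
  for (k in seq_len(max_tries)) {
    tries <- k
    cal_idx <- integer(0)
    for (j in seq_along(lev)) {
      members <- which(strata == lev[j])
      cal_idx <- c(cal_idx,
                   if (n_s[j] == 1) members
                   else sample(members, alloc[j]))
    }
    cal <- y[cal_idx]; val <- y[-cal_idx]
    d_mean <- abs(mean(cal) - mean(val))
    d_sd <- abs(stats::sd(cal) - stats::sd(val))
    score <- max(d_mean, d_sd) / sd_all
    if (score < best_score) {
      best_score <- score
      best <- list(cal_idx = cal_idx,
                   stats = c(d_mean = d_mean, d_sd = d_sd,
                             mean_cal = mean(cal), mean_val = mean(val),
                             sd_cal = stats::sd(cal), sd_val = stats::sd(val)))
    }
    if (d_mean <= tolerance * sd_all && d_sd <= tolerance * sd_all) {
      accepted <- TRUE
      break
    }
  }
  if (!accepted)
    warning("no candidate met the moment constraints in ", max_tries,
            " tries; returning the best one")
  structure(
    list(calibration_ids = as.character(rec$cow_id[best$cal_idx]),
         validation_ids = as.character(rec$cow_id[-best$cal_idx]),
         seed = seed, accepted = accepted, tries = tries,
         stats = best$stats),
    class = "split_plan")
}

#' Iterated external validation of a spectra-to-trait PLS model
#'
#' For each iteration: split the cows into calibration and validation sets
#' with [stratified_split()], tune the component count and drop
#' extreme-residual samples on the calibration set only, fit the final PLS
#' model there, and predict the untouched validation set. Reported fitting
#' statistics are the arithmetic mean over iterations; per-iteration values
#' are kept for audit. Centering and scaling inside the PLS are always
#' computed on calibration samples only, so no validation information leaks
#' into the model.
#'
#' @param spectra a preprocessed `SpectraSet` (absorbance, masked, SNV);
#'   sample ids must match `records$cow_id`.
#' @param records phenotype data frame (see [stratified_split()]).
#' @param trait trait column to predict.
#' @param n_iter number of external-validation iterations (default 3).
#' @param seeds integer seed per iteration (default `seq_len(n_iter)`); each
#'   iteration splits over a different random portion of cows.
#' @param max_lv latent-variable cap (default 20).
#' @param sd_threshold residual-outlier cutoff (default 3).
#' @param frac,tolerance,max_tries forwarded to [stratified_split()].
#' @param center,scale forwarded to the PLS fits (default: both on; turn
#'   `scale` off for spectra with constant regions, e.g. noiseless
#'   simulations).
#' @return A `fit_stats` list: averaged `r2_cv`, `rmse_cv`, `r2_val`,
#'   `rmse_val`, `pct_outliers_removed`, `n_lv`, plus `per_iteration`.
#' @export
external_validation <- function(spectra, records, trait, n_iter = 3,
                                seeds = seq_len(n_iter), max_lv = 20,
                                sd_threshold = 3, frac = 0.7,
                                tolerance = 0.1, max_tries = 200,
                                center = TRUE, scale = TRUE) {
  stopifnot(inherits(spectra, "SpectraSet"), length(seeds) == n_iter)
  rec <- records[!is.na(records[[trait]]), , drop = FALSE]
  idx <- match(as.character(rec$cow_id), spectra$sample_ids)
  if (anyNA(idx))
    stop("records without a matching spectrum: ",
         paste(utils::head(rec$cow_id[is.na(idx)], 5), collapse = ", "))
  X_all <- retained_matrix(spectra)[idx, , drop = FALSE]
  rownames(X_all) <- as.character(rec$cow_id)

  per <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    res <- tryCatch({
      plan <- stratified_split(rec, trait, frac = frac, seed = seeds[it],
                               max_tries = max_tries, tolerance = tolerance)
      cal <- match(plan$calibration_ids, rownames(X_all))
      val <- match(plan$validation_ids, rownames(X_all))
      Xc <- X_all[cal, , drop = FALSE]; yc <- rec[[trait]][cal]
      Xv <- X_all[val, , drop = FALSE]; yv <- rec[[trait]][val]
      mlv <- min(max_lv, nrow(Xc) - 2)
      ro <- remove_residual_outliers(Xc, yc, max_lv = mlv,
                                     sd_threshold = sd_threshold,
                                     center = center, scale = scale)
      Xk <- Xc[ro$keep, , drop = FALSE]; yk <- yc[ro$keep]
      cv <- loo_cv(Xk, yk, max_lv = mlv, center = center, scale = scale)
      fit <- fit_pls(Xk, yk, n_lv = cv$chosen_a, center = center,
                     scale = scale)
      st_cv <- fit_statistics(yk, cv$pred[, cv$chosen_a])
      st_val <- fit_statistics(yv, predict(fit, Xv))
      list(r2_cv = st_cv$r2, rmse_cv = st_cv$rmse,
           r2_val = st_val$r2, rmse_val = st_val$rmse,
           pct_outliers_removed = ro$pct_removed, n_lv = cv$chosen_a,
           split = plan)
    }, error = function(e) {
      stop("external validation iteration ", it, " failed: ",
           conditionMessage(e), call. = FALSE)
    })
    per[[it]] <- res
  }
  avg <- function(f) mean(vapply(per, `[[`, numeric(1), f))
  structure(
    list(r2_cv = avg("r2_cv"), rmse_cv = avg("rmse_cv"),
         r2_val = avg("r2_val"), rmse_val = avg("rmse_val"),
         pct_outliers_removed = avg("pct_outliers_removed"),
         n_lv = avg("n_lv"), n_iter = n_iter, per_iteration = per),
    class = "fit_stats")
}
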