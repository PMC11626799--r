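#' Read a phenotype record CSV
#'
#' One row per cow; requires `cow_id`, `herd_id` and either the class
#' factors (`parity_class`, `dim_class`, `season_class`) or the raw
#' `parity` / `dim` columns from which they are derived. Factor levels are
#' restored to their canonical order. SCS is derived from SCC when absent.
#'
#' @param path CSV path.
#' @return Phenotype data frame.
#' @export
read_records_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("cow_id", "herd_id") %in% names(d)))
    stop("records need cow_id and herd_id columns")
  if (!"parity_class" %in% names(d)) {
    if (!"parity" %in% names(d)) stop("need parity or parity_class")
    d$parity_class <- parity_class(d$parity)
  } else d$parity_class <- factor(d$parity_class, levels = c("1", "2", "3+"))
  if (!"dim_class" %in% names(d)) {
    if (!"dim" %in% names(d)) stop("need dim or dim_class")
    d$dim_class <- dim_class(d$dim)
  } else d$dim_class <- factor(d$dim_class,
                               levels = c("3-8", "9-14", "15-20", "21-38"))
  if ("season_class" %in% names(d))
    d$season_class <- factor(d$season_class,
                             levels = c("May-Jun", "Jul-Aug", "Sep-Oct"))
  if (!"scs" %in% names(d) && "scc" %in% names(d))
    d$scs <- compute_scs(d$scc)
  d
}

#' Phenotypic-variance workflow
#'
#' The full blood-trait variance analysis: 3-SD editing of milk and blood
#' traits, log10 transformation of the right-skewed traits, Spearman
#' correlation matrix between plasma traits and between plasma and milk
#' traits, one linear mixed model per blood trait (parity, DIM class, their
#' interaction, season; random herd) with Bonferroni-grouped least-squares
#' means (back-transformed for log traits), and the logistic odds-ratio
#' model for bilirubin binarized at 4 umol/L. Reports are written as CSV
#' plus a text log; per-stage sample counts are always logged.
#'
#' @param records phenotype data frame or path to a records CSV.
#' @param out_dir output directory (created if needed).
#' @param traits blood traits to model (default: all present).
#' @param bilt_cutoff bilirubin risk threshold in umol/L (default 4).
#' @return Invisibly, a list with the edited records, the per-trait
#'   `lmm_result`s, the correlation matrix and the odds-ratio table.
#' @export
run_phenovariance <- function(records, out_dir,
                              traits = NULL, bilt_cutoff = 4) {
  if (is.character(records)) records <- read_records_csv(records)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "phenovariance.log")
  logf <- function(...) cat(..., "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("phenovariance run | mirblood ",
       as.character(utils::packageVersion("mirblood")))
  logf("samples in: ", nrow(records))

  if (is.null(traits))
    traits <- intersect(blood_trait_names(), names(records))
  traits <- setdiff(traits, "blood_bilt")     # BILT is modelled as binary

  ed <- edit_records_3sd(records)
  rec <- ed$records
  utils::write.csv(ed$edits, file.path(out_dir, "editing_counts.csv"),
                   row.names = FALSE)
  logf("3-SD editing: ", sum(ed$edits$n_removed_low + ed$edits$n_removed_high),
       " values set missing across ", nrow(ed$edits), " traits")
  rec <- log10_transform(rec)

  corr_traits <- intersect(c(blood_trait_names(), milk_trait_names()),
                           names(rec))
  corr_traits <- setdiff(corr_traits, "blood_bilt")
  sm <- spearman_matrix(rec, corr_traits)
  utils::write.csv(round(sm$rho, 3),
                   file.path(out_dir, "spearman_rho.csv"))
  utils::write.csv(sm$stars, file.path(out_dir, "spearman_stars.csv"))

  lmms <- list()
  for (tr in traits) {
    fit <- fit_lmm(rec, tr)
    lmms[[tr]] <- fit
    tabs <- lapply(names(fit$lsm), function(v)
      cbind(factor = v, fit$lsm[[v]]))
    lsm_tab <- do.call(rbind, tabs)
    utils::write.csv(lsm_tab,
                     file.path(out_dir, paste0("lsm_", tr, ".csv")),
                     row.names = FALSE)
    utils::write.csv(fit$ftable,
                     file.path(out_dir, paste0("ftests_", tr, ".csv")),
                     row.names = FALSE)
    logf(tr, ": n = ", fit$n, ", sigma2_H = ",
         format(fit$sigma2_H, digits = 4), ", sigma2_e = ",
         format(fit$sigma2_e, digits = 4),
         if (fit$boundary) " (herd variance at boundary 0)" else "")
  }

  or_tab <- NULL
  if ("blood_bilt" %in% names(rec)) {
    lab <- label_by_threshold(rec$blood_bilt[!is.na(rec$blood_bilt)],
                              bilt_cutoff)
    rec$bilt_class <- NA_integer_
    rec$bilt_class[!is.na(rec$blood_bilt)] <- lab$labels
    or_tab <- fit_logistic_or(rec, "bilt_class")
    utils::write.csv(as.data.frame(or_tab),
                     file.path(out_dir, "bilt_odds_ratios.csv"),
                     row.names = FALSE)
    logf("BILT > ", bilt_cutoff, " umol/L prevalence: ",
         format(lab$prevalence_pct, digits = 4), "%")
  }
  logf("samples out: ", nrow(rec), " (editing sets values missing, never",
       " drops cows)")
  invisible(list(records = rec, lmm = lmms, spearman = sm,
                 odds_ratios = or_tab))
}

#' FT-MIR prediction and risk-classification workflow
#'
#' Preprocesses the spectra (absorbance conversion, water-region masking,
#' optional PCA outlier removal, SNV), then for each trait runs the
#' stratified iterated external validation of the PLS model and reports
#' percent residual outliers removed, latent-variable count, cross-validated
#' and external R2 / RMSE, and the R2 interpretation band. For each risk
#' threshold a PLS-DA is fitted on a stratified calibration set and
#' confusion metrics are reported for calibration and validation.
#'
#' @param records phenotype data frame or records CSV path.
#' @param spectra a `SpectraSet` or spectra CSV path (transmittance).
#' @param out_dir output directory.
#' @param traits traits to predict (default: blood urea, BHB, NEFA,
#'   glucose, cholesterol — the energy profile).
#' @param thresholds risk-threshold table (default
#'   [default_risk_thresholds()]).
#' @param n_iter,seeds,max_lv,sd_threshold validation settings (defaults:
#'   3 iterations, LV cap 20, 3-SD residual rule).
#' @param outlier_pcs,outlier_sd PCA spectral-outlier settings (5 PCs,
#'   3 SD); set `outlier_pcs = 0` to skip.
#' @return Invisibly, a list with the prediction table (`fit_table`), the
#'   classification table (`class_table`) and the preprocessed spectra.
#' @export
run_mir_prediction <- function(records, spectra, out_dir,
                               traits = c("blood_urea", "blood_bhb",
                                          "blood_nefa", "blood_glucose",
                                          "blood_cholesterol"),
                               thresholds = default_risk_thresholds(),
                               n_iter = 3, seeds = seq_len(n_iter),
                               max_lv = 20, sd_threshold = 3,
                               outlier_pcs = 5, outlier_sd = 3) {
  if (is.character(records)) records <- read_records_csv(records)
  if (is.character(spectra)) spectra <- read_spectra_csv(spectra)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "mir_prediction.log")
  logf <- function(...) cat(..., "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("mir_prediction run | mirblood ",
       as.character(utils::packageVersion("mirblood")),
       " | seeds ", paste(seeds, collapse = ","))

  unmatched <- setdiff(records$cow_id, spectra$sample_ids)
  if (length(unmatched))
    stop("records without a matching spectrum: ",
         paste(utils::head(unmatched, 5), collapse = ", "))

  sp <- transmittance_to_absorbance(spectra)
  sp <- suppressMessages(mask_water_regions(sp))
  logf("spectra in: ", nrow(sp$values), "; retained wavenumbers: ",
       sum(sp$retained_mask))
  if (outlier_pcs > 0) {
    flags <- detect_spectral_outliers(sp, n_pcs = outlier_pcs,
                                      score_sd_threshold = outlier_sd)
    logf("PCA spectral outliers flagged and removed: ", sum(flags))
    keep <- !flags
    sp$values <- sp$values[keep, , drop = FALSE]
    sp$sample_ids <- sp$sample_ids[keep]
    records <- records[records$cow_id %in% sp$sample_ids, , drop = FALSE]
  }
  sp <- snv(sp)

  fit_rows <- list()
  for (tr in traits) {
    fs <- external_validation(sp, records, tr, n_iter = n_iter,
                              seeds = seeds, max_lv = max_lv,
                              sd_threshold = sd_threshold)
    fit_rows[[tr]] <- data.frame(
      trait = tr,
      pct_outliers = round_half_up(fs$pct_outliers_removed, 1),
      n_lv = fs$n_lv,
      r2_cv = round_half_up(fs$r2_cv, 2),
      rmse_cv = signif(fs$rmse_cv, 3),
      r2_val = round_half_up(fs$r2_val, 2),
      rmse_val = signif(fs$rmse_val, 3),
      r2_band = classify_r2_band(min(1, max(0, fs$r2_cv))))
    logf(tr, ": r2_cv = ", round_half_up(fs$r2_cv, 2), ", r2_val = ",
         round_half_up(fs$r2_val, 2), ", mean LV = ", fs$n_lv)
  }
  fit_table <- do.call(rbind, fit_rows)
  names(fit_table) <- c("Blood trait", "% Outliers", "n. LV", "R2c",
                        "RMSEc", "R2v", "RMSEv", "R2 band")
  utils::write.csv(fit_table, file.path(out_dir, "pls_fit_statistics.csv"),
                   row.names = FALSE)

  class_rows <- list()
  for (i in seq_len(nrow(thresholds))) {
    tr <- thresholds$trait[i]; cut <- thresholds$cutoff[i]
    if (!tr %in% names(records)) next
    ok <- !is.na(records[[tr]])
    rec_t <- records[ok, , drop = FALSE]
    lab <- label_by_threshold(rec_t[[tr]], cut)
    if (length(unique(lab$labels)) < 2) {
      logf(tr, ": single-class labels at cutoff ", cut, "; skipped")
      next
    }
    rec_t$risk <- lab$labels
    plan <- stratified_split(rec_t, tr, seed = seeds[1])
    cal <- match(plan$calibration_ids, rec_t$cow_id)
    val <- match(plan$validation_ids, rec_t$cow_id)
    X <- retained_matrix(sp)[match(rec_t$cow_id, sp$sample_ids), ,
                             drop = FALSE]
    mdl <- fit_plsda(X[cal, , drop = FALSE], rec_t$risk[cal],
                     max_lv = max_lv)
    mc <- classification_metrics(rec_t$risk[cal],
                                 predict(mdl, X[cal, , drop = FALSE]))
    mv <- classification_metrics(rec_t$risk[val],
                                 predict(mdl, X[val, , drop = FALSE]))
    row <- function(set, m) data.frame(
      trait = tr, threshold = cut, set = set,
      prevalence_pct = round_half_up(lab$prevalence_pct, 1),
      sensitivity = round_half_up(m$sensitivity, 2),
      specificity = round_half_up(m$specificity, 2),
      ppv = round_half_up(m$ppv, 2), npv = round_half_up(m$npv, 2),
      balanced_accuracy = round_half_up(m$balanced_accuracy, 2))
    class_rows[[tr]] <- rbind(row("calibration", mc), row("validation", mv))
    logf(tr, " > ", cut, ": prevalence ",
         round_half_up(lab$prevalence_pct, 1), "%, balanced accuracy cal ",
         round_half_up(mc$balanced_accuracy, 2), " / val ",
         round_half_up(mv$balanced_accuracy, 2))
  }
  class_table <- if (length(class_rows)) do.call(rbind, class_rows) else NULL
  if (!is.null(class_table)) {
    names(class_table) <- c("Trait", "Threshold", "Set", "Prevalence %",
                            "Sensitivity", "Specificity", "PPV", "NPV",
                            "Balanced accuracy")
    utils::write.csv(class_table,
                     file.path(out_dir, "plsda_performance.csv"),
                     row.names = FALSE)
  }
  invisible(list(fit_table = fit_table, class_table = class_table,
                 spectra = sp))
}
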