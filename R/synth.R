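#' Configuration for the synthetic herd generator
#'
#' Defaults emulate the study design the pipeline is built for: 14
#' commercial herds, 349 clinically healthy cows sampled once at 3-38 days
#' in milk across three two-month seasons, blood-trait means and SDs as
#' observed pre-editing in early-lactation Holsteins (e.g. blood BHB
#' 0.71 +/- 0.54 mmol/L, NEFA 0.52 +/- 0.34 mmol/L, urea 4.19 +/- 1.31
#' mmol/L), right-skewed traits given log-normal marginals, and the
#' blood-blood and blood-milk rank-correlation structure (milk-blood urea
#' 0.89, milk-blood BHB 0.53, NEFA-urea 0.40, BHB-glucose -0.39, Na-Cl
#' 0.76, CK-AST 0.49, ...). Blood total bilirubin is parameterized so that
#' roughly 28% of cows exceed the 4 umol/L risk cutoff.
#'
#' @param n_herds number of herds (default 14).
#' @param n_cows number of cows (default 349).
#' @param herd_var_frac fraction of latent-trait variance shared within a
#'   herd (default 0.10).
#' @param dim_range sampling window in days in milk (default `c(3, 38)`).
#' @param dim_rate exponential-decay rate of the DIM distribution across the
#'   window (larger = more cows close to calving; default 0.07 gives a mean
#'   near 15 d).
#' @param parity_probs probabilities of parity classes 1, 2, >= 3.
#' @param season_probs probabilities of the May-Jun, Jul-Aug, Sep-Oct
#'   sampling seasons.
#' @param trait_means,trait_sds named overrides of per-trait marginal mean /
#'   SD on the observed (linear) scale.
#' @param spearman_targets data frame (`t1`, `t2`, `rho`) of target rank
#'   correlations; overrides/extends the defaults.
#' @param baseline,signature_amp mean absorbance offset and per-SD signature
#'   amplitude of the simulated spectra.
#' @param scatter_gain_sd SD of the per-sample multiplicative scatter gain
#'   (log scale); the gain multiplies the whole chemical absorbance, the
#'   effect SNV exists to remove.
#' @param scatter_slope_sd,scatter_offset_sd per-sample baseline tilt and
#'   offset SDs (absorbance units).
#' @param noise_sd i.i.d. spectral noise SD; inflated `water_noise_factor`
#'   times inside the discarded water intervals (default 50x) so masking
#'   demonstrably matters.
#' @param seed integer seed making every generated object deterministic.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_herds = 14, n_cows = 349, herd_var_frac = 0.10,
                         dim_range = c(3, 38), dim_rate = 0.07,
                         parity_probs = c(0.35, 0.30, 0.35),
                         season_probs = c(1, 1, 1) / 3,
                         trait_means = NULL, trait_sds = NULL,
                         spearman_targets = NULL,
                         baseline = 0.5, signature_amp = 0.08,
                         scatter_gain_sd = 0.1,
                         scatter_slope_sd = 0.02, scatter_offset_sd = 0.05,
                         noise_sd = 0.01, water_noise_factor = 50,
                         seed = 1) {
  specs <- default_trait_specs()
  if (!is.null(trait_means)) {
    stopifnot(all(names(trait_means) %in% specs$trait))
    specs$mean[match(names(trait_means), specs$trait)] <-
      as.numeric(trait_means)
  }
  if (!is.null(trait_sds)) {
    stopifnot(all(names(trait_sds) %in% specs$trait))
    specs$sd[match(names(trait_sds), specs$trait)] <- as.numeric(trait_sds)
  }
  if (any(specs$sd <= 0)) stop("trait SDs must be > 0")
  tg <- default_spearman_targets()
  if (!is.null(spearman_targets)) {
    stopifnot(all(c("t1", "t2", "rho") %in% names(spearman_targets)))
    for (i in seq_len(nrow(spearman_targets))) {
      hit <- (tg$t1 == spearman_targets$t1[i] &
                tg$t2 == spearman_targets$t2[i]) |
             (tg$t1 == spearman_targets$t2[i] &
                tg$t2 == spearman_targets$t1[i])
      if (any(hit)) tg$rho[hit] <- spearman_targets$rho[i]
      else tg <- rbind(tg, spearman_targets[i, c("t1", "t2", "rho")])
    }
  }
  structure(
    list(n_herds = n_herds, n_cows = n_cows, herd_var_frac = herd_var_frac,
         dim_range = dim_range, dim_rate = dim_rate,
         parity_probs = parity_probs / sum(parity_probs),
         season_probs = season_probs / sum(season_probs),
         trait_specs = specs, spearman_targets = tg,
         baseline = baseline, signature_amp = signature_amp,
         scatter_gain_sd = scatter_gain_sd,
         scatter_slope_sd = scatter_slope_sd,
         scatter_offset_sd = scatter_offset_sd,
         noise_sd = noise_sd, water_noise_factor = water_noise_factor,
         seed = seed),
    class = "synth_config")
}

# marginal means/SDs (observed linear scale) of the milk and blood traits;
# dist: "normal", "lognormal" (params derived from linear mean/sd), or
# "log10normal" (mean/sd are on the log10 scale, as milk BHB is reported)
default_trait_specs <- function() {
  d <- rbind(
    c("milk_yield",          39.04, 10.47,  "normal"),
    c("milk_fat",             4.39,  1.39,  "normal"),
    c("milk_protein",         3.34,  0.49,  "normal"),
    c("milk_casein",          2.57,  0.39,  "normal"),
    c("milk_lactose",         4.73,  0.26,  "normal"),
    c("scs",                  2.62,  2.09,  "normal"),
    c("milk_urea",           27.39,  7.85,  "normal"),
    c("milk_bhb",            -0.99,  0.24,  "log10normal"),
    c("blood_glucose",        2.80,  0.53,  "normal"),
    c("blood_cholesterol",    2.66,  0.92,  "normal"),
    c("blood_nefa",           0.52,  0.34,  "lognormal"),
    c("blood_bhb",            0.71,  0.54,  "lognormal"),
    c("blood_urea",           4.19,  1.31,  "normal"),
    c("blood_na",           138.88,  3.49,  "normal"),
    c("blood_k",              4.39,  0.39,  "normal"),
    c("blood_cl",            98.54,  3.77,  "normal"),
    c("blood_ca",             2.45,  0.15,  "normal"),
    c("blood_p",              1.60,  0.34,  "normal"),
    c("blood_mg",             0.96,  0.13,  "normal"),
    c("blood_total_protein", 74.37,  6.11,  "normal"),
    c("blood_albumin",       33.91,  4.34,  "normal"),
    c("blood_globulin",      40.46,  7.05,  "normal"),
    c("blood_ast",           98.14, 47.97,  "lognormal"),
    c("blood_ggt",           16.30,  9.74,  "lognormal"),
    c("blood_ck",           340.34, 694.34, "lognormal"),
    c("blood_bilt",           3.38,  1.80,  "lognormal"),
    c("blood_cortisol",      17.05, 15.00,  "lognormal"))
  data.frame(trait = d[, 1], mean = as.numeric(d[, 2]),
             sd = as.numeric(d[, 3]), dist = d[, 4],
             stringsAsFactors = FALSE)
}

# target rank correlations; unlisted pairs default to 0
default_spearman_targets <- function() {
  d <- rbind(
    c("milk_urea", "blood_urea",      0.89),
    c("milk_bhb",  "blood_bhb",       0.53),
    c("milk_bhb",  "blood_nefa",      0.30),
    c("milk_bhb",  "blood_glucose",  -0.30),
    c("blood_nefa", "blood_urea",     0.40),
    c("blood_bhb", "blood_glucose",  -0.39),
    c("blood_bhb", "blood_nefa",      0.26),
    c("blood_na",  "blood_cl",        0.76),
    c("blood_cl",  "blood_ca",       -0.29),
    c("blood_ck",  "blood_ast",       0.49),
    c("blood_urea", "blood_albumin",  0.40),
    c("blood_urea", "blood_globulin", -0.24),
    c("blood_albumin", "blood_ca",    0.30),
    c("blood_albumin", "blood_mg",    0.30),
    c("milk_yield", "blood_albumin",  0.51),
    c("milk_yield", "blood_p",       -0.24),
    c("blood_bilt", "blood_ast",      0.30),
    c("blood_bilt", "blood_nefa",     0.25))
  data.frame(t1 = d[, 1], t2 = d[, 2], rho = as.numeric(d[, 3]),
             stringsAsFactors = FALSE)
}

#' Latent Gaussian correlation matrix of a synthetic configuration
#'
#' Converts the target Spearman correlations to the Pearson correlations of
#' the Gaussian copula via `r = 2 sin(pi rho / 6)` (exact for bivariate
#' normals; rank correlations are invariant under the monotone marginal
#' transforms). If the assembled matrix is not positive semidefinite it is
#' repaired with the nearest correlation matrix (`Matrix::nearPD`), which is
#' reported via `message()`.
#'
#' @param cfg a `synth_config`.
#' @return Correlation matrix over the trait set.
#' @export
latent_correlation <- function(cfg) {
  traits <- cfg$trait_specs$trait
  k <- length(traits)
  R <- diag(k); dimnames(R) <- list(traits, traits)
  spec <- diag(k) > 0                 # which entries carry a target
  tg <- cfg$spearman_targets
  for (i in seq_len(nrow(tg))) {
    a <- match(tg$t1[i], traits); b <- match(tg$t2[i], traits)
    if (is.na(a) || is.na(b)) stop("unknown trait in spearman_targets")
    R[a, b] <- R[b, a] <- 2 * sin(pi * tg$rho[i] / 6)
    spec[a, b] <- spec[b, a] <- TRUE
  }
  # complete unspecified entries by transitive path products so that the
  # stated targets (e.g. milk-blood urea together with urea-NEFA) do not
  # force negative eigenvalues; specified targets are never touched
  known <- spec
  for (pass in 1:3) {
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      if (known[a, b]) next
      via <- which(known[a, ] & known[, b])
      via <- setdiff(via, c(a, b))
      if (!length(via)) next
      R[a, b] <- R[b, a] <- mean(R[a, via] * R[via, b])
    }
    known <- known | (R != 0)
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    message("correlation matrix not PSD (min eigenvalue ",
            format(min(ev), digits = 3), "); applying nearest-PSD repair")
    R <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
    dimnames(R) <- list(traits, traits)
  }
  R
}

#' Generate a herd-structured cow-record table
#'
#' Traits are drawn from a Gaussian copula with the configured target rank
#' correlations: a latent multivariate normal is split into a herd-level and
#' a cow-level draw (both with the same correlation structure) combined as
#' `sqrt(f) z_herd + sqrt(1 - f) z_cow` so a fraction `f` of latent variance
#' is shared within herd, then pushed through the configured marginals
#' (normal, log-normal, or log10-normal). Somatic cell count is derived from
#' the simulated SCS. Deterministic given `cfg$seed`.
#'
#' @param cfg a `synth_config`.
#' @return Data frame of cow records (one row per cow) with identifiers,
#'   design factors, milk traits and blood traits on the observed scale.
#' @export
generate_records <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  n <- cfg$n_cows; q <- cfg$n_herds
  specs <- cfg$trait_specs
  k <- nrow(specs)
  R <- latent_correlation(cfg)
  Rc <- chol(R)

  herd <- sort(sample(seq_len(q), n, replace = TRUE))
  # guarantee every herd is represented
  miss <- setdiff(seq_len(q), unique(herd))
  if (length(miss)) herd[sample(n, length(miss))] <- miss
  herd <- sort(herd)

  f <- cfg$herd_var_frac
  z_herd <- matrix(stats::rnorm(q * k), q, k) %*% Rc
  z_cow <- matrix(stats::rnorm(n * k), n, k) %*% Rc
  z <- sqrt(f) * z_herd[herd, , drop = FALSE] + sqrt(1 - f) * z_cow

  vals <- matrix(NA_real_, n, k, dimnames = list(NULL, specs$trait))
  for (j in seq_len(k)) {
    m <- specs$mean[j]; s <- specs$sd[j]
    vals[, j] <- switch(specs$dist[j],
      normal = m + s * z[, j],
      lognormal = {
        sdlog <- sqrt(log(1 + (s / m)^2))
        exp(log(m) - sdlog^2 / 2 + sdlog * z[, j])
      },
      log10normal = 10^(m + s * z[, j]),
      stop("unknown marginal: ", specs$dist[j]))
  }

  dims <- cfg$dim_range[1]:cfg$dim_range[2]
  dim_draw <- sample(dims, n, replace = TRUE,
                     prob = exp(-cfg$dim_rate * (dims - cfg$dim_range[1])))
  par_cls <- sample(c("1", "2", "3+"), n, replace = TRUE,
                    prob = cfg$parity_probs)
  parity <- ifelse(par_cls == "3+", sample(3:6, n, replace = TRUE),
                   as.integer(substr(par_cls, 1, 1)))
  season <- sample(c("May-Jun", "Jul-Aug", "Sep-Oct"), n, replace = TRUE,
                   prob = cfg$season_probs)

  rec <- data.frame(
    cow_id = sprintf("cow%03d", seq_len(n)),
    herd_id = sprintf("herd%02d", herd),
    parity = parity,
    parity_class = parity_class(parity),
    dim = dim_draw,
    dim_class = dim_class(dim_draw),
    season_class = factor(season,
                          levels = c("May-Jun", "Jul-Aug", "Sep-Oct")),
    stringsAsFactors = FALSE)
  rec <- cbind(rec, as.data.frame(vals))
  rec$scc <- scs_to_scc(rec$scs)
  rec
}

# fixed smooth absorbance signatures: Gaussian bumps (in cm^-1) centered
# inside the retained windows, one signature per spectrally visible analyte
spectral_signatures <- function(axis) {
  bump <- function(center, width) exp(-0.5 * ((axis - center) / width)^2)
  list(
    blood_urea    = bump(1465, 20) + 0.6 * bump(1160, 25),
    blood_bhb     = bump(1745, 18) + 0.5 * bump(1300, 22),
    blood_nefa    = bump(2855, 30) + 0.7 * bump(2925, 25),
    blood_glucose = bump(1035, 18) + 0.5 * bump(1080, 15),
    blood_bilt    = bump(1560, 15) + 0.4 * bump(2550, 20),
    milk_fat      = bump(1755, 15) + 0.8 * bump(2870, 35),
    milk_protein  = bump(1540, 25) + 0.6 * bump(1240, 20),
    milk_lactose  = bump(1060, 22) + 0.5 * bump(985, 18))
}

#' Generate milk FT-MIR-like transmittance spectra for a record table
#'
#' Beer-Lambert-style linear mixing: per-sample absorbance is a baseline
#' plus the sum over spectrally visible analytes of the standardized
#' concentration times a fixed smooth signature (Gaussian bumps centered in
#' the retained windows), plus a per-sample scatter term (random tilt x
#' normalized wavenumber + random offset) and i.i.d. noise whose SD is
#' inflated inside the discarded water intervals. Absorbance is converted
#' to transmittance `T = 10^-A`, clipped into `(0, 1]`. Deterministic given
#' `cfg$seed` (offset from the record stream so records and spectra are
#' independently reproducible).
#'
#' @param records output of [generate_records()].
#' @param cfg the same `synth_config`.
#' @param analytes which trait columns drive the spectrum; default: the
#'   eight built-in signatures.
#' @return A `SpectraSet` in transmittance mode on the 1,060-point
#'   5,000-900 cm^-1 grid.
#' @export
generate_spectra <- function(records, cfg,
                             analytes = names(spectral_signatures(1))) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 1e6)
  axis <- build_wavenumber_grid(1060, 5000, 900)
  sig <- spectral_signatures(axis)[analytes]
  n <- nrow(records)
  A <- matrix(cfg$baseline, n, length(axis))
  for (nm in names(sig)) {
    v <- records[[nm]]
    spec <- cfg$trait_specs[cfg$trait_specs$trait == nm, ]
    # standardize on the latent (log for skewed marginals) scale
    z <- if (nrow(spec) && spec$dist %in% c("lognormal", "log10normal")) {
      lv <- log(v); (lv - mean(lv)) / stats::sd(lv)
    } else {
      (v - mean(v)) / stats::sd(v)
    }
    A <- A + cfg$signature_amp * tcrossprod(z, sig[[nm]])
  }
  ax_norm <- (axis - mean(axis)) / (max(axis) - min(axis))
  gain <- exp(stats::rnorm(n, 0, cfg$scatter_gain_sd))
  slope <- stats::rnorm(n, 0, cfg$scatter_slope_sd)
  offset <- stats::rnorm(n, 0, cfg$scatter_offset_sd)
  A <- gain * A + tcrossprod(slope, ax_norm) + offset

  water <- !mask_only(axis, default_retained_regions())
  sd_vec <- ifelse(water, cfg$noise_sd * cfg$water_noise_factor, cfg$noise_sd)
  if (cfg$noise_sd > 0)
    A <- A + matrix(stats::rnorm(n * length(axis)), n) %*% diag(sd_vec)

  Tm <- 10^(-A)
  Tm[Tm > 1] <- 1
  Tm[Tm < 1e-6] <- 1e-6
  spectra_set(Tm, axis, records$cow_id, mode = "transmittance")
}

# boolean retained mask for an axis without constructing a SpectraSet
mask_only <- function(axis, regions) {
  iv <- regions$intervals
  mask <- rep(FALSE, length(axis))
  for (i in seq_len(nrow(iv)))
    mask <- mask | (axis >= iv[i, "low"] & axis <= iv[i, "high"])
  mask
}

#' Write a paired records + spectra fixture suite
#'
#' Writes a small (n = 60) and a full-scale (n = 349) paired CSV fixture,
#' plus a JSON manifest recording the seed and a hash of the configuration;
#' reruns with the same configuration are byte-identical.
#'
#' @param out_dir writable output directory (created if needed).
#' @param cfg full-scale `synth_config` (default [synth_config()]).
#' @param n_small size of the small fixture (default 60).
#' @return Invisibly, the five file paths written.
#' @export
generate_fixture_suite <- function(out_dir, cfg = synth_config(),
                                   n_small = 60) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_small <- cfg
  cfg_small$n_cows <- n_small
  cfg_small$n_herds <- min(cfg$n_herds, max(2, n_small %/% 10))
  sets <- list(small = cfg_small, full = cfg)
  paths <- character(0)
  for (nm in names(sets)) {
    rec <- generate_records(sets[[nm]])
    sp <- generate_spectra(rec, sets[[nm]])
    rp <- file.path(out_dir, paste0("records_", nm, ".csv"))
    sp_path <- file.path(out_dir, paste0("spectra_", nm, ".csv"))
    utils::write.csv(rec, rp, row.names = FALSE)
    write_spectra_csv(sp, sp_path)
    paths <- c(paths, rp, sp_path)
  }
  manifest <- file.path(out_dir, "manifest.json")
  writeLines(sprintf(
    '{"seed": %d, "n_small": %d, "n_full": %d, "config_hash": "%s"}',
    cfg$seed, n_small, cfg$n_cows, config_hash(cfg)), manifest)
  invisible(c(paths, manifest))
}

#' FNV-1a hash of a configuration
#'
#' A short stable fingerprint of a `synth_config` used in fixture
#' manifests; changes whenever any configuration field changes.
#'
#' @param cfg a `synth_config` (or any serializable object).
#' @return 8-hex-digit character hash.
#' @export
config_hash <- function(cfg) {
  bytes <- as.integer(serialize(cfg, NULL, version = 2))
  # 32-bit FNV-1a in double arithmetic: split the multiply so every
  # intermediate stays below 2^53
  h <- 2166136261
  for (b in bytes) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), b)   # xor touches the low byte only
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
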