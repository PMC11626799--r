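#' Milk FT-MIR spectra container
#'
#' A `SpectraSet` bundles a wavenumber axis (cm^-1, strictly descending, as
#' recorded by FT-MIR milk analyzers scanning from 5,000 down to 900 cm^-1),
#' a per-cow matrix of spectral values, the mode of those values
#' (transmittance or absorbance), and a logical mask of the points retained
#' after discarding the water-absorption regions.
#'
#' @param values numeric matrix, one row per sample, one column per
#'   wavenumber. Transmittance values must be strictly positive.
#' @param axis numeric vector of wavenumbers in cm^-1, strictly descending,
#'   of length `ncol(values)`.
#' @param sample_ids character or integer identifiers, one per row. Defaults
#'   to the rownames of `values`, or `1:nrow` when absent.
#' @param mode `"transmittance"` or `"absorbance"`.
#' @param retained_mask logical vector per axis point; defaults to all `TRUE`
#'   (no water-region masking applied yet).
#' @return An object of class `SpectraSet`.
#' @seealso [transmittance_to_absorbance()], [mask_water_regions()], [snv()]
#' @export
spectra_set <- function(values, axis, sample_ids = NULL,
                        mode = c("transmittance", "absorbance"),
                        retained_mask = NULL) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  if (length(axis) != ncol(values))
    stop("axis length (", length(axis), ") must equal the number of value columns (",
         ncol(values), ")")
  if (length(axis) >= 2 && any(diff(axis) >= 0))
    stop("axis must be strictly monotone descending")
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- as.character(seq_len(nrow(values)))
  }
  if (length(sample_ids) != nrow(values))
    stop("sample_ids length must equal the number of rows")
  if (mode == "transmittance" && any(values <= 0, na.rm = TRUE)) {
    bad <- sample_ids[apply(values <= 0, 1, any)]
    stop("transmittance must be > 0; offending sample(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (is.null(retained_mask)) retained_mask <- rep(TRUE, length(axis))
  if (length(retained_mask) != length(axis))
    stop("retained_mask length must equal axis length")
  structure(
    list(sample_ids = as.character(sample_ids), axis = as.numeric(axis),
         values = unname(values), mode = mode,
         retained_mask = as.logical(retained_mask)),
    class = "SpectraSet")
}

#' @export
print.SpectraSet <- function(x, ...) {
  cat("SpectraSet:", nrow(x$values), "samples x", length(x$axis), "points (",
      x$mode, ")\n")
  cat("  axis:", format(x$axis[1]), "->", format(x$axis[length(x$axis)]),
      "cm^-1\n")
  cat("  retained points:", sum(x$retained_mask), "of", length(x$axis), "\n")
  invisible(x)
}

#' @export
dim.SpectraSet <- function(x) dim(x$values)

#' Retained-columns matrix of a SpectraSet
#'
#' @param s a `SpectraSet`.
#' @return Numeric matrix restricted to the retained wavenumber columns, with
#'   sample ids as rownames.
#' @export
retained_matrix <- function(s) {
  stopifnot(inherits(s, "SpectraSet"))
  m <- s$values[, s$retained_mask, drop = FALSE]
  rownames(m) <- s$sample_ids
  colnames(m) <- format(s$axis[s$retained_mask], trim = TRUE)
  m
}

#' Build a linear, descending wavenumber grid
#'
#' FT-MIR milk analyzers record a fixed number of points between two
#' wavenumber endpoints; the grid here is linear, descending, with both
#' endpoints included — the only reproducible convention when the instrument
#' grid is not published.
#'
#' @param n_points number of grid points (>= 2).
#' @param start_cm1 first wavenumber (cm^-1); must exceed `end_cm1`.
#' @param end_cm1 last wavenumber (cm^-1).
#' @return Numeric vector of length `n_points`, equally spaced, descending.
#' @examples
#' ax <- build_wavenumber_grid(1060, 5000, 900)
#' range(ax)
#' @export
build_wavenumber_grid <- function(n_points = 1060, start_cm1 = 5000,
                                  end_cm1 = 900) {
  if (length(n_points) != 1 || n_points < 2 || n_points != round(n_points))
    stop("n_points must be a single integer >= 2")
  if (start_cm1 <= end_cm1)
    stop("start_cm1 must be greater than end_cm1 (descending grid)")
  seq(start_cm1, end_cm1, length.out = n_points)
}

#' Convert transmittance spectra to absorbance
#'
#' Applies A = log10(1/T) pointwise (Beer-Lambert absorbance from the
#' fraction of radiation transmitted).
#'
#' @param s a `SpectraSet` in transmittance mode with all values > 0.
#' @return The same `SpectraSet` in absorbance mode.
#' @export
transmittance_to_absorbance <- function(s) {
  stopifnot(inherits(s, "SpectraSet"))
  if (s$mode != "transmittance")
    stop("spectra are already in absorbance mode")
  if (any(s$values <= 0)) {
    bad <- s$sample_ids[apply(s$values <= 0, 1, any)]
    stop("transmittance must be > 0; offending sample(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  s$values <- log10(1 / s$values)
  s$mode <- "absorbance"
  s
}

#' Convert absorbance spectra back to transmittance
#'
#' Inverse of [transmittance_to_absorbance()]: T = 10^(-A).
#'
#' @param s a `SpectraSet` in absorbance mode.
#' @return The same `SpectraSet` in transmittance mode.
#' @export
absorbance_to_transmittance <- function(s) {
  stopifnot(inherits(s, "SpectraSet"))
  if (s$mode != "absorbance") stop("spectra are not in absorbance mode")
  s$values <- 10^(-s$values)
  s$mode <- "transmittance"
  s
}

#' Default retained wavenumber regions
#'
#' The three spectral windows conventionally kept after discarding the
#' regions dominated by water absorption in milk mid-infrared spectra:
#' 945.5-1,585.6, 1,716.8-1,929.0 and 2,507.7-2,970.7 cm^-1 (closed
#' intervals).
#'
#' @return A `RetainedRegions` object: a list with an `intervals` matrix
#'   (columns `low`, `high`).
#' @export
default_retained_regions <- function() {
  retained_regions(rbind(c(945.5, 1585.6),
                         c(1716.8, 1929.0),
                         c(2507.7, 2970.7)))
}

#' Construct a set of retained wavenumber intervals
#'
#' @param intervals two-column numeric matrix (or coercible) of closed
#'   `(low, high)` wavenumber pairs in cm^-1; intervals must be disjoint with
#'   `low < high`.
#' @return A `RetainedRegions` object.
#' @export
retained_regions <- function(intervals) {
  intervals <- matrix(as.numeric(as.matrix(intervals)), ncol = 2)
  colnames(intervals) <- c("low", "high")
  if (any(intervals[, "low"] >= intervals[, "high"]))
    stop("each interval needs low < high")
  o <- order(intervals[, "low"])
  iv <- intervals[o, , drop = FALSE]
  if (nrow(iv) > 1 && any(iv[-1, "low"] <= iv[-nrow(iv), "high"]))
    stop("intervals must be disjoint")
  structure(list(intervals = intervals), class = "RetainedRegions")
}

#' Mask water-absorption regions of a spectrum set
#'
#' Marks as retained exactly the axis points falling inside any of the given
#' closed intervals; all downstream modelling uses only retained columns.
#'
#' @param s a `SpectraSet`.
#' @param regions a `RetainedRegions` object; defaults to
#'   [default_retained_regions()].
#' @return `s` with `retained_mask` set. The retained count is reported via
#'   `message()`.
#' @export
mask_water_regions <- function(s, regions = default_retained_regions()) {
  stopifnot(inherits(s, "SpectraSet"), inherits(regions, "RetainedRegions"))
  iv <- regions$intervals
  mask <- rep(FALSE, length(s$axis))
  for (i in seq_len(nrow(iv)))
    mask <- mask | (s$axis >= iv[i, "low"] & s$axis <= iv[i, "high"])
  if (!any(mask)) stop("no axis point falls inside the retained intervals")
  s$retained_mask <- mask
  message("retained ", sum(mask), " of ", length(mask), " wavenumber points")
  s
}

#' Standard normal variate (SNV) scatter correction
#'
#' Standardizes each spectrum to mean 0 and unit sample SD (n-1 denominator)
#' over the retained points, removing per-sample baseline offset and
#' multiplicative scatter. Non-retained columns are standardized with the
#' same per-spectrum statistics so that masking and SNV commute on the
#' retained block.
#'
#' @param s a `SpectraSet` in absorbance mode with >= 2 retained points.
#' @return `s` with each spectrum standardized.
#' @export
snv <- function(s) {
  stopifnot(inherits(s, "SpectraSet"))
  if (s$mode != "absorbance")
    stop("SNV is applied to absorbance spectra; convert first")
  if (sum(s$retained_mask) < 2)
    stop("SNV needs at least 2 retained points per spectrum")
  x <- s$values[, s$retained_mask, drop = FALSE]
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  if (any(sdv == 0))
    stop("zero-variance spectrum; sample(s): ",
         paste(s$sample_ids[sdv == 0], collapse = ", "))
  s$values <- (s$values - mu) / sdv
  s
}

#' Flag anomalous spectra by PCA score distance
#'
#' Principal components are extracted from the centered retained-absorbance
#' matrix; a sample is flagged when any of its first `n_pcs` scores lies more
#' than `score_sd_threshold` standard deviations from that score's mean.
#' Flags are returned, never silently dropped.
#'
#' @param s a `SpectraSet` (absorbance recommended).
#' @param n_pcs number of leading components to inspect (default 5).
#' @param score_sd_threshold score-distance threshold in SD units (default 3).
#' @return Logical vector, one flag per sample, named by sample id.
#' @export
detect_spectral_outliers <- function(s, n_pcs = 5, score_sd_threshold = 3) {
  stopifnot(inherits(s, "SpectraSet"))
  x <- retained_matrix(s)
  n <- nrow(x)
  if (n_pcs < 1 || n_pcs >= n)
    stop("need n_samples > n_pcs >= 1 (n = ", n, ", n_pcs = ", n_pcs, ")")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)
  sc <- pc$x[, seq_len(min(n_pcs, ncol(pc$x))), drop = FALSE]
  z <- scale(sc)                      # per-score mean 0, sd 1
  z[, attr(z, "scaled:scale") == 0] <- 0   # degenerate (constant) scores
  flags <- apply(abs(z) > score_sd_threshold, 1, any)
  names(flags) <- s$sample_ids
  flags
}

#' Read spectra from the CSV dialect
#'
#' The dialect: a header row holding the wavenumber axis, a first column of
#' sample ids, and one row of spectral values per cow. The axis must be
#' strictly descending.
#'
#' @param path CSV file path.
#' @param mode `"transmittance"` (default) or `"absorbance"`.
#' @param n_points_expected optional check on the axis length.
#' @return A `SpectraSet`.
#' @export
read_spectra_csv <- function(path, mode = c("transmittance", "absorbance"),
                             n_points_expected = NULL) {
  mode <- match.arg(mode)
  d <- utils::read.csv(path, check.names = FALSE)
  ids <- as.character(d[[1]])
  axis <- as.numeric(names(d)[-1])
  if (anyNA(axis)) stop("header row must be numeric wavenumbers")
  if (!is.null(n_points_expected) && length(axis) != n_points_expected)
    stop("expected ", n_points_expected, " points, found ", length(axis))
  spectra_set(as.matrix(d[, -1, drop = FALSE]), axis, ids, mode = mode)
}

#' Write spectra in the CSV dialect
#'
#' @param s a `SpectraSet`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(s, path) {
  stopifnot(inherits(s, "SpectraSet"))
  d <- data.frame(sample_id = s$sample_ids, s$values, check.names = FALSE)
  names(d) <- c("sample_id", format(s$axis, trim = TRUE, digits = 10))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
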