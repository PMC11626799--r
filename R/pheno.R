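#' Trait-column naming scheme
#'
#' All phenotype tables use one row per cow with identifiers (`cow_id`,
#' `herd_id`), design factors (`parity_class`, `dim`, `dim_class`,
#' `season_class`), `milk_*` columns for milk traits and `blood_*` columns
#' for plasma traits.
#'
#' @return Character vector of the blood-trait column names.
#' @export
blood_trait_names <- function() {
  c("blood_glucose", "blood_cholesterol", "blood_nefa", "blood_bhb",
    "blood_urea", "blood_na", "blood_k", "blood_cl", "blood_ca", "blood_p",
    "blood_mg", "blood_total_protein", "blood_albumin", "blood_globulin",
    "blood_ast", "blood_ggt", "blood_ck", "blood_bilt", "blood_cortisol")
}

#' Milk-trait column names
#' @return Character vector.
#' @export
milk_trait_names <- function() {
  c("milk_yield", "milk_fat", "milk_protein", "milk_casein", "milk_lactose",
    "scs", "milk_urea", "milk_bhb")
}

#' Blood traits that are log10-transformed before modelling
#' @return Character vector.
#' @export
log_trait_names <- function() {
  c("blood_bhb", "blood_nefa", "blood_ast", "blood_ggt", "blood_ck",
    "blood_cortisol")
}

#' Days-in-milk class
#'
#' Four early-lactation classes: 3-8, 9-14, 15-20 and 21-38 days in milk.
#'
#' @param dim integer days in milk, 3..38.
#' @return Factor with levels `"3-8" < "9-14" < "15-20" < "21-38"`.
#' @export
dim_class <- function(dim) {
  if (any(dim < 3 | dim > 38, na.rm = TRUE))
    stop("days in milk must lie in 3..38")
  cut(dim, breaks = c(2, 8, 14, 20, 38),
      labels = c("3-8", "9-14", "15-20", "21-38"))
}

#' Parity class
#'
#' @param parity integer lactation number (>= 1).
#' @return Factor with levels `"1"`, `"2"`, `"3+"` (third class pools
#'   parities 3 and above).
#' @export
parity_class <- function(parity) {
  if (any(parity < 1, na.rm = TRUE)) stop("parity must be >= 1")
  factor(ifelse(parity >= 3, "3+", as.character(parity)),
         levels = c("1", "2", "3+"))
}

#' Somatic cell score
#'
#' SCS = 3 + log2(SCC / 100,000), the standard log transform of the somatic
#' cell count.
#'
#' @param scc somatic cell count in cells/mL, > 0.
#' @return Numeric SCS.
#' @export
compute_scs <- function(scc) {
  if (any(scc <= 0, na.rm = TRUE)) stop("SCC must be > 0")
  3 + log2(scc / 1e5)
}

#' Inverse of [compute_scs()]
#' @param scs somatic cell score.
#' @return SCC in cells/mL.
#' @export
scs_to_scc <- function(scs) 1e5 * 2^(scs - 3)

#' Mark values more than 3 SD from the mean as missing
#'
#' The mean and SD are computed once, on the original vector (single pass);
#' values with |x - mean| > 3 SD become `NA`. With zero SD nothing is
#' removed.
#'
#' @param values numeric vector with >= 3 non-missing values.
#' @param n_sd the cutoff multiplier (default 3).
#' @return List with the edited `values`, `n_removed_low`, `n_removed_high`.
#' @export
edit_outliers_3sd <- function(values, n_sd = 3) {
  ok <- !is.na(values)
  if (sum(ok) < 3) stop("need at least 3 non-missing values")
  m <- mean(values[ok]); s <- stats::sd(values[ok])
  if (s == 0)
    return(list(values = values, n_removed_low = 0L, n_removed_high = 0L))
  low <- ok & (values < m - n_sd * s)
  high <- ok & (values > m + n_sd * s)
  values[low | high] <- NA
  list(values = values, n_removed_low = sum(low), n_removed_high = sum(high))
}

#' Apply 3-SD editing to a set of trait columns
#'
#' @param records phenotype data frame.
#' @param traits trait columns to edit (default: all milk and blood traits
#'   present).
#' @return List with the edited `records` and a per-trait `edits` table of
#'   removal counts.
#' @export
edit_records_3sd <- function(records,
                             traits = intersect(c(milk_trait_names(),
                                                  blood_trait_names()),
                                                names(records))) {
  edits <- data.frame(trait = traits, n_removed_low = 0L, n_removed_high = 0L)
  for (i in seq_along(traits)) {
    e <- edit_outliers_3sd(records[[traits[i]]])
    records[[traits[i]]] <- e$values
    edits$n_removed_low[i] <- e$n_removed_low
    edits$n_removed_high[i] <- e$n_removed_high
  }
  list(records = records, edits = edits)
}

#' Log10-transform the non-normal blood traits
#'
#' Replaces the named columns by their log10 values and records the
#' transformed names so least-squares means can be back-transformed with
#' `10^x`.
#'
#' @param records phenotype data frame.
#' @param traits columns to transform (default [log_trait_names()]).
#' @return `records` with transformed columns and attribute
#'   `"log10_traits"` listing them.
#' @export
log10_transform <- function(records, traits = log_trait_names()) {
  traits <- intersect(traits, names(records))
  for (tr in traits) {
    v <- records[[tr]]
    bad <- !is.na(v) & v <= 0
    if (any(bad))
      stop("non-positive ", tr, " for cow(s): ",
           paste(utils::head(records$cow_id[bad], 5), collapse = ", "))
    records[[tr]] <- log10(v)
  }
  attr(records, "log10_traits") <-
    union(attr(records, "log10_traits"), traits)
  records
}

#' Spearman correlation matrix with pairwise-complete observations
#'
#' Mid-rank ties; p-values from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 df; significance stars
#' at 0.05 (*), 0.01 (**) and 0.001 (***). Cells with a constant trait or
#' fewer than 3 complete pairs are `NA`.
#'
#' @param records phenotype data frame.
#' @param traits trait columns to correlate.
#' @return A `spearman_matrix` list with matrices `rho`, `n`, `p`, `stars`.
#' @export
spearman_matrix <- function(records, traits) {
  stopifnot(all(traits %in% names(records)))
  k <- length(traits)
  rho <- n <- p <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  for (i in seq_len(k)) for (j in i:k) {
    x <- records[[traits[i]]]; y <- records[[traits[j]]]
    ok <- !is.na(x) & !is.na(y)
    n[i, j] <- n[j, i] <- sum(ok)
    if (sum(ok) < 3) next
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
    r <- stats::cor(x[ok], y[ok], method = "spearman")
    rho[i, j] <- rho[j, i] <- r
    if (i == j) { p[i, j] <- NA_real_; next }
    if (abs(r) >= 1) { p[i, j] <- p[j, i] <- 0; next }
    tv <- r * sqrt((sum(ok) - 2) / (1 - r^2))
    p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tv), sum(ok) - 2)
  }
  stars <- matrix("", k, k, dimnames = list(traits, traits))
  stars[!is.na(p) & p <= 0.05] <- "*"
  stars[!is.na(p) & p <= 0.01] <- "**"
  stars[!is.na(p) & p <= 0.001] <- "***"
  structure(list(rho = rho, n = n, p = p, stars = stars),
            class = "spearman_matrix")
}
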