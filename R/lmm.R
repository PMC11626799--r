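#' Linear mixed model with a random herd effect, fitted by REML
#'
#' Fits `y = mu + parity + DIM class + parity x DIM + season + herd + e`
#' (the default fixed structure; any fixed formula over the record columns
#' can be supplied) with the herd intercept random, `H ~ N(0, sigma2_H)`,
#' and residuals `e ~ N(0, sigma2_e)`. Estimation profiles the variance
#' ratio `lambda = sigma2_H / sigma2_e`: for fixed lambda the fixed effects
#' have a closed-form GLS solution and the residual variance a closed-form
#' REML estimate, so the restricted likelihood is maximized by a
#' one-dimensional search over log(lambda), with the boundary `sigma2_H = 0`
#' checked explicitly and flagged when attained.
#'
#' Fixed-effect factors use sum-to-zero contrasts, so the Wald test on a
#' term's coefficients is the type-III F test; denominator degrees of
#' freedom are `n - rank(X)`. Least-squares means average the model
#' prediction over the full factor grid; all pairwise within-factor
#' contrasts are Bonferroni-adjusted (`p_adj = min(1, m p)`, `m` the number
#' of pairs) with compact-letter grouping at p <= 0.05. For log10-scale
#' traits the LSM are additionally back-transformed as `10^LSM`.
#'
#' @param records phenotype data frame; rows with a missing value in the
#'   trait or any model factor are dropped (listwise).
#' @param trait response column name.
#' @param fixed one-sided fixed-effects formula (default
#'   `~ parity_class * dim_class + season_class`).
#' @param herd name of the herd (random-effect) column, default `"herd_id"`.
#' @param backtransform report `10^LSM` columns; defaults to `TRUE` when
#'   `trait` is listed in the records' `"log10_traits"` attribute.
#' @return An `lmm_result` with `sigma2_H`, `sigma2_e`, `lambda`,
#'   `boundary`, `beta`, `vcov`, `ftable`, `lsm` (one data frame per
#'   factor), `n`, `rank`.
#' @export
fit_lmm <- function(records, trait,
                    fixed = ~ parity_class * dim_class + season_class,
                    herd = "herd_id", backtransform = NULL) {
  stopifnot(trait %in% names(records), herd %in% names(records))
  if (is.null(backtransform))
    backtransform <- trait %in% (attr(records, "log10_traits") %||% character(0))
  vars <- all.vars(fixed)
  stopifnot(all(vars %in% names(records)))
  d <- records[stats::complete.cases(records[, c(trait, herd, vars),
                                            drop = FALSE]), , drop = FALSE]
  for (v in vars) d[[v]] <- droplevels(as.factor(d[[v]]))
  d[[herd]] <- droplevels(as.factor(d[[herd]]))
  if (nlevels(d[[herd]]) < 2) stop("need at least 2 herds")
  y <- d[[trait]]
  n <- length(y)

  ctr <- if (length(vars)) {
    cl <- lapply(d[vars], function(x) "contr.sum")
    names(cl) <- vars
    cl
  } else NULL
  mf <- stats::model.frame(fixed, d)
  X <- stats::model.matrix(fixed, mf, contrasts.arg = ctr)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  p <- ncol(X)
  hid <- as.integer(d[[herd]])
  n_h <- tabulate(hid)

  # GLS pieces for V = I + lambda Z Z' via Woodbury (Z'Z is diagonal)
  gls <- function(lambda) {
    dh <- lambda / (1 + lambda * n_h)
    vinv <- function(M) {
      M <- as.matrix(M)
      M - (dh[hid] * rowsum(M, hid)[hid, , drop = FALSE])
    }
    XtViX <- crossprod(X, vinv(X))
    XtViy <- crossprod(X, vinv(y))
    beta <- solve(XtViX, XtViy)
    r <- y - as.numeric(X %*% beta)
    q <- sum(r * vinv(r))
    list(beta = as.numeric(beta), XtViX = XtViX, q = q,
         logdetV = sum(log1p(lambda * n_h)))
  }
  neg2reml <- function(lambda) {
    g <- gls(lambda)
    (n - p) * log(g$q) + g$logdetV + determinant(g$XtViX)$modulus[1]
  }
  opt <- stats::optimize(function(th) neg2reml(exp(th)),
                         interval = c(-15, 8))
  lambda <- exp(opt$minimum)
  boundary <- FALSE
  if (neg2reml(0) <= opt$objective + 1e-8) {
    lambda <- 0; boundary <- TRUE
  }
  g <- gls(lambda)
  sigma2_e <- g$q / (n - p)
  sigma2_H <- lambda * sigma2_e
  vcov_beta <- sigma2_e * solve(g$XtViX)
  beta <- g$beta
  names(beta) <- colnames(X)

  # type-III F tests per term (sum-to-zero contrasts)
  asgn <- attr(stats::model.matrix(fixed, mf, contrasts.arg = ctr), "assign")
  asgn <- asgn[match(colnames(X),
                     colnames(stats::model.matrix(fixed, mf,
                                                  contrasts.arg = ctr)))]
  labs <- attr(stats::terms(fixed), "term.labels")
  ftable <- if (length(labs))
    data.frame(term = labs, df1 = NA_real_, df2 = n - p, F = NA_real_,
               p = NA_real_)
  else data.frame(term = character(0), df1 = numeric(0), df2 = numeric(0),
                  F = numeric(0), p = numeric(0))
  for (i in seq_along(labs)) {
    idx <- which(asgn == i)
    if (!length(idx)) next
    b <- beta[idx]
    Fv <- as.numeric(crossprod(b, solve(vcov_beta[idx, idx, drop = FALSE],
                                        b))) / length(idx)
    ftable$df1[i] <- length(idx)
    ftable$F[i] <- Fv
    ftable$p[i] <- stats::pf(Fv, length(idx), n - p, lower.tail = FALSE)
  }

  # least-squares means over the full factor grid
  lsm <- list()
  if (length(vars)) {
    grid <- expand.grid(lapply(mf[vars], levels), KEEP.OUT.ATTRS = FALSE)
    names(grid) <- vars
    Xg <- stats::model.matrix(fixed, grid, contrasts.arg = ctr)
    Xg <- Xg[, colnames(X), drop = FALSE]
  }
  for (v in vars) {
    levs <- levels(mf[[v]])
    L <- t(vapply(levs, function(l) colMeans(Xg[grid[[v]] == l, ,
                                                drop = FALSE]),
                  numeric(ncol(Xg))))
    est <- as.numeric(L %*% beta)
    se <- sqrt(diag(L %*% vcov_beta %*% t(L)))
    pw <- pairwise_bonferroni(est, L, vcov_beta, n - p)
    tab <- data.frame(level = levs, estimate = est, se = se,
                      letters = cld_letters(est, pw$sig))
    if (backtransform) tab$estimate_bt <- 10^est
    lsm[[v]] <- tab
  }

  structure(
    list(trait = trait, sigma2_H = sigma2_H, sigma2_e = sigma2_e,
         lambda = lambda, boundary = boundary, beta = beta,
         vcov = vcov_beta, ftable = ftable, lsm = lsm, n = n, rank = p,
         backtransformed = backtransform),
    class = "lmm_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# all pairwise contrasts L[i,] - L[j,]; Bonferroni within the factor
pairwise_bonferroni <- function(est, L, vcov_beta, df) {
  k <- length(est)
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  p_raw <- p_adj <- numeric(m)
  for (j in seq_len(m)) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    l <- L[i1, ] - L[i2, ]
    se <- sqrt(as.numeric(t(l) %*% vcov_beta %*% l))
    tv <- (est[i1] - est[i2]) / se
    p_raw[j] <- 2 * stats::pt(-abs(tv), df)
    p_adj[j] <- min(1, m * p_raw[j])
  }
  sig <- matrix(FALSE, k, k)
  for (j in seq_len(m))
    sig[pairs[1, j], pairs[2, j]] <- sig[pairs[2, j], pairs[1, j]] <-
      p_adj[j] <= 0.05
  list(pairs = pairs, p_raw = p_raw, p_adj = p_adj, sig = sig)
}

# compact letter display: maximal cliques of the "not significantly
# different" graph, letters ordered by descending estimate (a = highest)
cld_letters <- function(est, sig) {
  k <- length(est)
  if (k > 16) stop("compact letters support up to 16 levels")
  compat <- !sig; diag(compat) <- TRUE
  subsets <- list()
  for (code in seq_len(2^k) - 1L) {
    members <- which(bitwAnd(code, 2^(seq_len(k) - 1)) > 0)
    if (length(members) < 1) next
    ok <- all(compat[members, members])
    if (ok) subsets[[length(subsets) + 1]] <- members
  }
  maximal <- Filter(function(s) {
    !any(vapply(subsets, function(t)
      length(t) > length(s) && all(s %in% t), logical(1)))
  }, subsets)
  # order cliques by the highest member estimate so 'a' marks the top group
  ord <- order(-vapply(maximal, function(s) max(est[s]), numeric(1)))
  maximal <- maximal[ord]
  lets <- rep("", k)
  for (i in seq_along(maximal))
    lets[maximal[[i]]] <- paste0(lets[maximal[[i]]], letters[i])
  if (all(lets == lets[1])) lets[] <- ""   # no separation: no letters shown
  lets
}

#' @export
print.lmm_result <- function(x, ...) {
  cat("Linear mixed model for", x$trait, "(REML, random herd)\n")
  cat("  sigma2_H =", format(x$sigma2_H, digits = 4),
      " sigma2_e =", format(x$sigma2_e, digits = 4),
      if (x$boundary) " [boundary: herd variance 0]" else "", "\n")
  cat("  n =", x$n, " fixed-effect rank =", x$rank, "\n\nType-III tests:\n")
  print(x$ftable, row.names = FALSE)
  invisible(x)
}

#' Logistic odds ratios for a binarized blood trait
#'
#' Fits a binomial logistic regression of the binary outcome on parity
#' class, DIM class and season (main effects), with herd as a fixed effect,
#' via iteratively reweighted least squares (`glm`). Odds ratios per factor
#' level are relative to the reference (first) level with Wald 95%
#' confidence intervals computed on the log-odds scale and exponentiated;
#' a level is significant when its CI excludes 1. Complete separation is
#' flagged per level and its CI reported as unbounded.
#'
#' @param records phenotype data frame.
#' @param binary_trait name of a 0/1 outcome column.
#' @param factors factor columns to report (default parity, DIM class,
#'   season).
#' @param herd herd column treated as a fixed effect (default `"herd_id"`).
#' @return An `or_result` data frame: `factor`, `level`, `or`, `ci_low`,
#'   `ci_high`, `significant`, `reference`, `separation`.
#' @export
fit_logistic_or <- function(records, binary_trait,
                            factors = c("parity_class", "dim_class",
                                        "season_class"),
                            herd = "herd_id") {
  stopifnot(binary_trait %in% names(records),
            all(factors %in% names(records)))
  d <- records[stats::complete.cases(
    records[, c(binary_trait, herd, factors), drop = FALSE]), , drop = FALSE]
  yv <- d[[binary_trait]]
  if (length(unique(yv)) < 2) stop("both outcome classes must be present")
  for (v in c(factors, herd)) d[[v]] <- droplevels(as.factor(d[[v]]))
  rhs <- c(factors, if (nlevels(d[[herd]]) >= 2) herd)
  fml <- stats::reformulate(rhs, response = binary_trait)
  fit <- suppressWarnings(stats::glm(fml, data = d,
                                     family = stats::binomial()))
  cf <- summary(fit)$coefficients
  out <- list()
  for (v in factors) {
    levs <- levels(d[[v]])
    rows <- data.frame(factor = v, level = levs, or = 1, ci_low = NA_real_,
                       ci_high = NA_real_, significant = FALSE,
                       reference = c(TRUE, rep(FALSE, length(levs) - 1)),
                       separation = FALSE)
    for (i in seq_along(levs)[-1]) {
      nm <- paste0(v, levs[i])
      if (!nm %in% rownames(cf)) next
      b <- cf[nm, "Estimate"]; se <- cf[nm, "Std. Error"]
      sep <- abs(b) > 10 || se > 100     # diverging coefficient
      rows$separation[i] <- sep
      rows$or[i] <- exp(b)
      if (sep) {
        rows$ci_low[i] <- 0; rows$ci_high[i] <- Inf
      } else {
        rows$ci_low[i] <- exp(b - 1.96 * se)
        rows$ci_high[i] <- exp(b + 1.96 * se)
        rows$significant[i] <- rows$ci_low[i] > 1 || rows$ci_high[i] < 1
      }
    }
    out[[v]] <- rows
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("or_result", "data.frame")
  attr(res, "fit") <- fit
  res
}
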