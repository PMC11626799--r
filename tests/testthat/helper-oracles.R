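# Independent oracles used across the suite. Each is coded by a different
# route than the implementation it checks.

# PLS1 coefficients via the Krylov-subspace identity: with centered/scaled
# X and centered y, the a-component PLS coefficient vector is the
# least-squares solution restricted to span{s, Cs, ..., C^(a-1) s} with
# s = X'y, C = X'X. Completely independent of the NIPALS deflation route.
oracle_pls_predict <- function(Xtrain, ytrain, Xnew, a) {
  mu <- colMeans(Xtrain)
  sdv <- apply(Xtrain, 2, sd)
  Xs <- scale(Xtrain, center = mu, scale = sdv)
  yc <- ytrain - mean(ytrain)
  s <- crossprod(Xs, yc)
  C <- crossprod(Xs)
  K <- matrix(NA_real_, ncol(Xs), a)
  v <- s
  for (j in seq_len(a)) {
    K[, j] <- v
    v <- C %*% v
  }
  qrK <- qr(K)
  K <- qr.Q(qrK)[, seq_len(qrK$rank), drop = FALSE]
  b <- K %*% solve(crossprod(K, C %*% K), crossprod(K, s))
  Xn <- scale(Xnew, center = mu, scale = sdv)
  as.numeric(Xn %*% b) + mean(ytrain)
}

# mid-ranks computed by explicit position averaging (no rank())
oracle_midrank <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n))
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  r
}

oracle_spearman <- function(x, y) {
  rx <- oracle_midrank(x); ry <- oracle_midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# closed-form odds ratio of a 2x2 table: (a d) / (b c)
oracle_or_2x2 <- function(exposed_case, exposed_ctrl,
                          unexposed_case, unexposed_ctrl) {
  (exposed_case * unexposed_ctrl) / (exposed_ctrl * unexposed_case)
}

# tiny SpectraSet builders
toy_spectra <- function(values, axis = NULL, mode = "transmittance") {
  values <- as.matrix(values)
  if (is.null(axis)) axis <- seq(ncol(values), 1)
  spectra_set(values, axis, mode = mode)
}

# minimal record table with the design columns required by the split
toy_records <- function(n, herds = 4, trait = rnorm(n)) {
  data.frame(cow_id = sprintf("c%03d", seq_len(n)),
             herd_id = rep_len(sprintf("h%02d", seq_len(herds)), n),
             parity_class = parity_class(rep_len(c(1, 2, 3), n)),
             dim_class = dim_class(rep_len(c(5, 12, 18, 30), n)),
             season_class = factor(rep_len(c("May-Jun", "Jul-Aug",
                                             "Sep-Oct"), n),
                                   levels = c("May-Jun", "Jul-Aug",
                                              "Sep-Oct")),
             y = trait)
}
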