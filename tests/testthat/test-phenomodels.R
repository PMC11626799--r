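test_that("3-SD editing removes the normal tail mass and nothing else", {
  set.seed(50)
  v <- rnorm(10000)
  e <- edit_outliers_3sd(v)
  rate <- (e$n_removed_low + e$n_removed_high) / 10000
  expect_gt(rate, 0.0005)
  expect_lt(rate, 0.006)                 # ~0.27% expected

  # the single extreme value inflates the SD enough to save itself:
  # mean 25, sd 50, so |100 - 25| = 75 < 150
  e2 <- edit_outliers_3sd(c(0, 0, 0, 100))
  expect_equal(e2$n_removed_low + e2$n_removed_high, 0L)

  e3 <- edit_outliers_3sd(rep(7, 5))
  expect_identical(e3$values, rep(7, 5))
})

test_that("editing statistics come from a single pass on the raw vector", {
  v <- c(rnorm(50), 40, 80)              # 80 is extreme even with 40 present
  m <- mean(v); s <- sd(v)
  e <- edit_outliers_3sd(v)
  expect_identical(is.na(e$values), abs(v - m) > 3 * s)
})

test_that("log10 transform matches known values and round-trips", {
  rec <- data.frame(cow_id = c("a", "b", "c"),
                    blood_bhb = c(1, 0.1, 0.102))
  out <- log10_transform(rec, "blood_bhb")
  expect_equal(out$blood_bhb, c(0, -1, log10(0.102)))
  expect_equal(out$blood_bhb[3], -0.99, tolerance = 0.01)
  expect_equal(10^out$blood_bhb, rec$blood_bhb, tolerance = 1e-12)
  expect_true("blood_bhb" %in% attr(out, "log10_traits"))
  rec$blood_bhb[2] <- 0
  expect_error(log10_transform(rec, "blood_bhb"), "b")
})

test_that("somatic cell score follows its defining transform", {
  expect_equal(compute_scs(1e5), 3)
  expect_equal(compute_scs(4e5), 5)
  expect_equal(compute_scs(5e4), 2)
  expect_equal(scs_to_scc(compute_scs(237000)), 237000, tolerance = 1e-9)
  expect_error(compute_scs(0))
})

test_that("class factors follow the study design", {
  expect_equal(as.character(dim_class(c(3, 8, 9, 14, 15, 20, 21, 38))),
               c("3-8", "3-8", "9-14", "9-14", "15-20", "15-20",
                 "21-38", "21-38"))
  expect_error(dim_class(2))
  expect_equal(as.character(parity_class(c(1, 2, 3, 10))),
               c("1", "2", "3+", "3+"))
})

test_that("Spearman matrix: monotone invariance, ties, independence bound", {
  set.seed(51)
  x <- rnorm(30)
  rec <- data.frame(a = x, b = exp(x), c = -x^3)
  sm <- spearman_matrix(rec, c("a", "b", "c"))
  expect_equal(sm$rho["a", "b"], 1)
  expect_equal(sm$rho["a", "c"], -1)
  expect_equal(diag(sm$rho), rep(1, 3), ignore_attr = TRUE)
  expect_equal(sm$rho, t(sm$rho))

  # mid-rank tie handling against the exhaustive rank oracle
  u <- c(1, 2, 2, 3, 5, 5)
  v <- c(2, 1, 4, 4, 6, 7)
  sm2 <- spearman_matrix(data.frame(u = u, v = v), c("u", "v"))
  expect_equal(sm2$rho["u", "v"], oracle_spearman(u, v), tolerance = 1e-12)

  set.seed(52)
  big <- data.frame(p = rnorm(10000), q = rnorm(10000))
  sm3 <- spearman_matrix(big, c("p", "q"))
  expect_lt(abs(sm3$rho["p", "q"]), 0.05)
  expect_gt(sm3$p["p", "q"], 0.001)      # no spurious significance
})

test_that("constant traits and sparse pairs give missing cells", {
  rec <- data.frame(a = c(1, 2, 3, 4), b = c(2, 2, 2, 2),
                    c = c(1, NA, NA, NA))
  sm <- spearman_matrix(rec, c("a", "b", "c"))
  expect_true(is.na(sm$rho["a", "b"]))
  expect_true(is.na(sm$rho["a", "c"]))
  expect_equal(sm$n["a", "c"], 1)
})

test_that("REML matches lme4 on small random datasets", {
  set.seed(53)
  for (rep in 1:20) {
    q <- sample(4:8, 1)
    n_per <- sample(4:8, 1)
    herd <- rep(seq_len(q), each = n_per)
    f <- factor(rep_len(c("u", "v"), q * n_per))
    y <- 2 + (f == "v") * 0.8 + rnorm(q, sd = runif(1, 0.3, 1.5))[herd] +
      rnorm(q * n_per)
    rec <- data.frame(cow_id = seq_along(y), herd_id = herd, f = f, y = y)
    fit <- fit_lmm(rec, "y", fixed = ~ f, backtransform = FALSE)
    lfit <- suppressMessages(
      lme4::lmer(y ~ f + (1 | herd_id), data = rec, REML = TRUE,
                 contrasts = list(f = "contr.sum")))
    vc <- as.data.frame(lme4::VarCorr(lfit))
    expect_equal(fit$sigma2_H, vc$vcov[1], tolerance = 1e-4)
    expect_equal(fit$sigma2_e, vc$vcov[2], tolerance = 1e-4)
    expect_equal(unname(fit$beta[1]), unname(lme4::fixef(lfit)[1]),
                 tolerance = 1e-4)
  }
})

test_that("zero herd signal collapses to OLS with boundary flag", {
  set.seed(54)
  rec <- data.frame(cow_id = 1:150,
                    herd_id = sample(sprintf("h%02d", 1:6), 150,
                                     replace = TRUE),
                    parity_class = parity_class(sample(1:3, 150,
                                                       replace = TRUE)),
                    y = rnorm(150))
  fit <- fit_lmm(rec, "y", fixed = ~ parity_class, backtransform = FALSE)
  expect_lt(fit$sigma2_H / fit$sigma2_e, 0.15)
  ols <- lm(y ~ parity_class, data = rec,
            contrasts = list(parity_class = "contr.sum"))
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 0.05)
})

test_that("balanced one-factor LSM equal raw level means", {
  set.seed(55)
  f <- rep(c("1", "2", "3+"), each = 20)
  rec <- data.frame(cow_id = 1:60,
                    herd_id = rep(c("h1", "h2"), 30),
                    parity_class = factor(f, levels = c("1", "2", "3+")),
                    y = rnorm(60) + rep(c(0, 1, 3), each = 20))
  fit <- fit_lmm(rec, "y", fixed = ~ parity_class, backtransform = FALSE)
  raw <- as.numeric(tapply(rec$y, rec$parity_class, mean))
  # with negligible herd variance LSM reduce to the raw level means
  expect_equal(fit$lsm$parity_class$estimate, raw, tolerance = 0.05)
  # clear separation earns distinct letters for the extreme levels
  lets <- fit$lsm$parity_class$letters
  expect_false(grepl(substr(lets[3], 1, 1), lets[1]))
})

test_that("Bonferroni adjustment multiplies by the contrast count", {
  est <- c(0, 0.5, 2)
  L <- diag(3)
  v <- diag(3) * 0.09
  pw <- mirblood:::pairwise_bonferroni(est, L, v, df = 30)
  expect_equal(pw$p_adj, pmin(1, 3 * pw$p_raw))
  expect_true(all(pw$p_adj >= pw$p_raw))
})

test_that("back-transformed LSM equal geometric means in the balanced case", {
  set.seed(56)
  f <- rep(c("a", "b"), each = 16)
  y_raw <- rlnorm(32, meanlog = rep(c(0, 1), each = 16), sdlog = 0.4)
  rec <- data.frame(cow_id = 1:32, herd_id = rep(c("h1", "h2"), 16),
                    g = factor(f), blood_bhb = y_raw)
  rec <- log10_transform(rec, "blood_bhb")
  fit <- fit_lmm(rec, "blood_bhb", fixed = ~ g)
  expect_true(fit$backtransformed)
  geo <- as.numeric(tapply(y_raw, f, function(v) exp(mean(log(v)))))
  expect_equal(fit$lsm$g$estimate_bt, geo, tolerance = 0.02)
})

test_that("REML recovers the variance components of a herd design", {
  set.seed(57)
  q <- 14; n_per <- 25
  herd <- rep(seq_len(q), each = n_per)
  sH <- sG <- numeric(60)
  for (r in 1:60) {
    y <- 10 + rnorm(q, sd = 2)[herd] + rnorm(q * n_per, sd = 1)
    rec <- data.frame(cow_id = seq_along(y), herd_id = herd, y = y)
    fit <- fit_lmm(rec, "y", fixed = ~ 1, backtransform = FALSE)
    sH[r] <- fit$sigma2_H; sG[r] <- fit$sigma2_e
  }
  expect_equal(mean(sH), 4, tolerance = 0.1)
  expect_equal(mean(sG), 1, tolerance = 0.05)
})

test_that("logistic odds ratio equals the closed-form 2x2 value", {
  rec <- data.frame(
    cow_id = 1:60,
    herd_id = "h1",
    exposed = factor(rep(c("no", "yes"), each = 30)),
    out = c(rep(1, 10), rep(0, 20),    # unexposed: 10 cases / 20 controls
            rep(1, 20), rep(0, 10)))   # exposed:   20 cases / 10 controls
  or <- fit_logistic_or(rec, "out", factors = "exposed")
  got <- or$or[or$level == "yes"]
  expect_equal(got, oracle_or_2x2(20, 10, 10, 20), tolerance = 1e-6)
  expect_equal(got, 4, tolerance = 1e-6)
})

test_that("independent outcome gives OR near 1 with covering CI", {
  set.seed(58)
  rec <- data.frame(
    cow_id = 1:300,
    herd_id = sample(sprintf("h%02d", 1:4), 300, replace = TRUE),
    parity_class = parity_class(sample(1:3, 300, replace = TRUE)),
    dim_class = dim_class(sample(3:38, 300, replace = TRUE)),
    season_class = factor(sample(c("May-Jun", "Jul-Aug", "Sep-Oct"), 300,
                                 replace = TRUE)))
  rec$out <- rbinom(300, 1, 0.3)
  or <- fit_logistic_or(rec, "out")
  nonref <- or[!or$reference & !or$separation, ]
  expect_true(all(nonref$ci_low < 1 & nonref$ci_high > 1))
})

test_that("a strong parity effect is recovered across replicates", {
  set.seed(59)
  n <- 349
  hit <- logical(120)
  true_or <- 3.85
  for (r in seq_along(hit)) {
    par_cls <- sample(c("1", "2", "3+"), n, replace = TRUE)
    eta <- -1 + log(true_or) * (par_cls == "3+") +
      rnorm(10, sd = 0.3)[rep_len(1:10, n)]
    rec <- data.frame(cow_id = 1:n,
                      herd_id = rep_len(sprintf("h%02d", 1:10), n),
                      parity_class = factor(par_cls,
                                            levels = c("1", "2", "3+")),
                      out = rbinom(n, 1, plogis(eta)))
    or <- fit_logistic_or(rec, "out", factors = "parity_class")
    row <- or[or$level == "3+", ]
    hit[r] <- !row$separation && row$ci_low <= true_or &&
      row$ci_high >= true_or
  }
  expect_gte(mean(hit), 0.9)
})
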