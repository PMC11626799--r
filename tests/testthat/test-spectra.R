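test_that("wavenumber grid is linear, descending, endpoint-inclusive", {
  ax <- build_wavenumber_grid(1060, 5000, 900)
  expect_equal(ax[1], 5000)
  expect_equal(ax[1060], 900)
  expect_equal(unique(round(-diff(ax), 10)), round(4100 / 1059, 10))
  expect_equal(build_wavenumber_grid(2, 10, 0), c(10, 0))
  expect_equal(build_wavenumber_grid(3, 4, 0), c(4, 2, 0))
  expect_error(build_wavenumber_grid(1, 10, 0))
  expect_error(build_wavenumber_grid(5, 0, 10))
})

test_that("transmittance/absorbance conversion and round trip", {
  s <- toy_spectra(rbind(c(1, 0.1, 0.01)))
  a <- transmittance_to_absorbance(s)
  expect_equal(a$values, rbind(c(0, 1, 2)))
  expect_equal(a$mode, "absorbance")
  back <- absorbance_to_transmittance(a)
  expect_equal(back$values, s$values, tolerance = 1e-12)
  # round trip the other way from absorbance
  set.seed(1)
  s2 <- toy_spectra(matrix(runif(40, 0.05, 0.95), 4))
  rt <- absorbance_to_transmittance(transmittance_to_absorbance(s2))
  expect_lt(max(abs(rt$values - s2$values) / s2$values), 1e-12)
})

test_that("non-positive transmittance is rejected with the sample id", {
  expect_error(spectra_set(rbind(a = c(1, 1), b = c(1, -1)), c(2, 1)), "b")
  s <- toy_spectra(rbind(c(0.5, 0.5)))
  s$values[1, 1] <- 0
  expect_error(transmittance_to_absorbance(s), "sample")
})

test_that("water-region masking retains exactly the in-interval points", {
  ax <- build_wavenumber_grid(1060, 5000, 900)
  s <- spectra_set(matrix(0.5, 2, 1060), ax)
  expect_message(m <- mask_water_regions(s), "340 of 1060")
  expect_equal(sum(m$retained_mask), 340)
  iv <- default_retained_regions()$intervals
  inside <- rep(FALSE, 1060)
  for (i in 1:3) inside <- inside | (ax >= iv[i, 1] & ax <= iv[i, 2])
  expect_identical(m$retained_mask, inside)

  s3 <- spectra_set(matrix(1, 1, 3), c(3000, 2000, 1000))
  m3 <- suppressMessages(
    mask_water_regions(s3, retained_regions(cbind(1500, 2500))))
  expect_identical(m3$retained_mask, c(FALSE, TRUE, FALSE))

  all_in <- suppressMessages(
    mask_water_regions(s3, retained_regions(cbind(500, 3500))))
  expect_true(all(all_in$retained_mask))
  expect_error(suppressMessages(
    mask_water_regions(s3, retained_regions(cbind(10, 20)))))
})

test_that("masking commutes with absorbance conversion", {
  set.seed(2)
  s <- toy_spectra(matrix(runif(60, 0.1, 0.9), 3),
                   axis = seq(2000, 100, length.out = 20))
  reg <- retained_regions(rbind(c(300, 800), c(1200, 1700)))
  a_then_m <- suppressMessages(
    mask_water_regions(transmittance_to_absorbance(s), reg))
  m_then_a <- transmittance_to_absorbance(suppressMessages(
    mask_water_regions(s, reg)))
  expect_identical(a_then_m$retained_mask, m_then_a$retained_mask)
  expect_equal(retained_matrix(a_then_m), retained_matrix(m_then_a))
})

test_that("SNV standardizes, is affine-invariant and idempotent", {
  s <- toy_spectra(rbind(c(1, 2, 3)), mode = "absorbance")
  expect_equal(snv(s)$values, rbind(c(-1, 0, 1)))

  set.seed(3)
  x <- matrix(rnorm(50), 2)
  plain <- toy_spectra(x, mode = "absorbance")
  affine <- toy_spectra(3.7 * x + 11, mode = "absorbance")
  expect_equal(snv(affine)$values, snv(plain)$values, tolerance = 1e-12)

  once <- snv(plain)
  expect_equal(snv(once)$values, once$values, tolerance = 1e-12)

  flat <- toy_spectra(rbind(c(5, 5, 5)), mode = "absorbance")
  expect_error(snv(flat), "zero-variance")
})

test_that("SNV statistics come from retained points only", {
  set.seed(4)
  s <- toy_spectra(matrix(rnorm(40), 2), mode = "absorbance",
                   axis = seq(2000, 100, length.out = 20))
  s <- suppressMessages(mask_water_regions(s,
                                           retained_regions(cbind(500, 1500))))
  out <- snv(s)
  kept <- retained_matrix(out)
  expect_equal(rowMeans(kept), c(`1` = 0, `2` = 0), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(apply(kept, 1, sd), c(1, 1), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("PCA outlier flags find gross baseline shifts, ignore offsets", {
  set.seed(5)
  n <- 40; p <- 30
  x <- matrix(rnorm(n * p, sd = 0.01), n, p)
  x[7, ] <- x[7, ] + 1          # baseline offset 100x the noise SD
  s <- toy_spectra(x, mode = "absorbance")
  flags <- detect_spectral_outliers(s, n_pcs = 3)
  expect_true(flags[7])
  expect_equal(sum(flags), 1)

  # column-constant offsets are absorbed by centering
  s2 <- toy_spectra(sweep(x, 2, seq_len(p)), mode = "absorbance")
  expect_identical(detect_spectral_outliers(s2, n_pcs = 3), flags)

  # near-identical spectra: nothing flagged at threshold 3
  s3 <- toy_spectra(matrix(1, 10, 5) +
                      matrix(rnorm(50, sd = 1e-14), 10),
                    mode = "absorbance")
  expect_false(any(detect_spectral_outliers(s3, n_pcs = 2)))

  expect_error(detect_spectral_outliers(s, n_pcs = n))
})

test_that("i.i.d. Gaussian spectra are flagged near the 3-SD tail rate", {
  set.seed(6)
  s <- toy_spectra(matrix(rnorm(200 * 50), 200), mode = "absorbance")
  rate <- mean(detect_spectral_outliers(s, n_pcs = 5))
  # per-score two-sided 3-SD tail across 5 scores: ~1 - (1 - 0.0027)^5
  expect_gt(rate, 0)
  expect_lt(rate, 0.06)
})

test_that("spectra CSV dialect round-trips", {
  set.seed(7)
  s <- toy_spectra(matrix(runif(30, 0.2, 0.9), 3),
                   axis = seq(1500, 600, length.out = 10))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(s, path)
  r <- read_spectra_csv(path, n_points_expected = 10)
  expect_equal(r$axis, s$axis)
  expect_equal(r$values, s$values, tolerance = 1e-8)
  expect_identical(r$sample_ids, s$sample_ids)
  expect_error(read_spectra_csv(path, n_points_expected = 338), "found 10")
})
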