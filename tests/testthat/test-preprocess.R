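make_axis_dataset <- function(axis, ...) {
  rows <- list(...)
  spectral_dataset(do.call(rbind, rows), axis,
                   sprintf("s%d", seq_along(rows)),
                   rep("case", length(rows)),
                   seq_along(rows))
}

test_that("cut_region keeps the closed interval exactly", {
  axis <- seq(600, 4000, 4)
  ds <- make_axis_dataset(axis, axis / 1000)
  cut <- cut_region(ds, 900, 1800)
  expect_equal(length(cut$axis), 226)
  expect_equal(range(cut$axis), c(900, 1800))

  ident <- cut_region(ds, 600, 4000)
  expect_equal(ident$absorbance, ds$absorbance)

  single <- cut_region(ds, 1648, 1648)
  expect_equal(single$axis, 1648)
  expect_equal(ncol(single$absorbance), 1)

  expect_error(cut_region(ds, 5000, 6000), "no wavenumbers")
})

test_that("Savitzky-Golay reproduces low-order polynomials exactly", {
  axis <- seq(900, 1800, 4)
  const <- rep(2.5, length(axis))
  quad <- 3e-6 * axis^2 - 4e-3 * axis + 2
  ds <- make_axis_dataset(axis, const, quad)
  sm <- savgol_smooth(ds, 15, 2)
  expect_equal(sm$absorbance[1, ], const, tolerance = 1e-12)
  expect_lt(max(abs(sm$absorbance[2, ] - quad)), 1e-9)
})

test_that("impulse response equals the least-squares kernel centre", {
  # oracle: explicit order-2 LS fit over a symmetric 15-point window
  A <- outer(-7:7, 0:2, `^`)
  H <- A %*% solve(crossprod(A)) %*% t(A)
  center_coef <- H[8, 8]

  axis <- seq(1000, by = 4, length.out = 31)
  impulse <- numeric(31); impulse[16] <- 1
  ds <- make_axis_dataset(axis, impulse)
  sm <- savgol_smooth(ds, 15, 2)
  expect_equal(sm$absorbance[1, 16], center_coef, tolerance = 1e-10)
})

test_that("Savitzky-Golay input validation", {
  ds <- make_axis_dataset(seq(1000, by = 4, length.out = 20),
                          rnorm(20))
  expect_error(savgol_smooth(ds, 14, 2), "odd")
  expect_error(savgol_smooth(ds, 21, 2), "exceeds")
  expect_error(savgol_smooth(cut_region(ds, 1000, 1000), 15, 2),
               "exceeds")
})

test_that("AWLS removes pure polynomial baselines", {
  axis <- seq(900, 1800, 4)
  t <- 2 * (axis - mean(axis)) / diff(range(axis))
  poly4 <- 0.3 + 0.2 * t - 0.1 * t^2 + 0.05 * t^3 + 0.02 * t^4
  ds <- make_axis_dataset(axis, poly4)
  out <- awls_baseline(ds, awls_degree = 4)
  expect_lt(max(abs(out$absorbance)), 1e-8)
})

test_that("AWLS is invariant to constant offsets", {
  axis <- seq(900, 1800, 4)
  peaks <- band_profile(rbind(band_spec(1100, 8, 1),
                              band_spec(1650, 10, 0.8)), axis)
  ds <- make_axis_dataset(axis, peaks)
  ds_off <- make_axis_dataset(axis, peaks + 0.37)
  a <- awls_baseline(ds, awls_tol = 1e-10)$absorbance
  b <- awls_baseline(ds_off, awls_tol = 1e-10)$absorbance
  expect_lt(max(abs(a - b)), 1e-8)
})

test_that("AWLS recovers planted peaks over a drifting baseline", {
  axis <- seq(900, 1800, 4)
  t <- 2 * (axis - mean(axis)) / diff(range(axis))
  baseline <- 0.5 + 0.1 * t + 0.05 * t^2 - 0.04 * t^3
  bands <- rbind(band_spec(1100, 6, 1), band_spec(1400, 6, 0.8),
                 band_spec(1650, 6, 0.9))
  peaks <- band_profile(bands, axis)
  ds <- make_axis_dataset(axis, baseline + peaks)
  out <- awls_baseline(ds)$absorbance[1, ]
  peak_free <- abs(axis - 1100) > 24 & abs(axis - 1400) > 24 &
    abs(axis - 1650) > 24
  expect_lt(max(abs(out[peak_free] - peaks[peak_free])), 0.02)
  # baseline is only ever subtracted, never added
  expect_true(all(out <= baseline + peaks + 1e-8))
})

test_that("AWLS rejects degenerate degrees and warns on non-convergence", {
  ds <- tiny_dataset(n = 1, p = 5)
  expect_error(awls_baseline(ds, awls_degree = 5), "smaller")
  axis <- seq(900, 1800, 4)
  wiggly <- make_axis_dataset(axis, abs(sin(axis / 15)) + 0.2)
  expect_warning(awls_baseline(wiggly, awls_max_iter = 2,
                               awls_tol = 1e-12), "converge")
})

test_that("band normalisation pins the anchor window maximum at 1", {
  axis <- seq(900, 1800, 4)
  spec <- band_profile(rbind(band_spec(1650, 20, 0.8),
                             band_spec(1100, 10, 0.5)), axis)
  ds <- make_axis_dataset(axis, spec, 5 * spec, 2.7 * spec)
  nm <- normalize_to_band(ds)
  win <- axis >= 1640 & axis <= 1660
  expect_equal(apply(nm$absorbance[, win], 1, max), rep(1, 3))
  # scale invariance: all three rows identical after normalisation
  expect_lt(max(abs(nm$absorbance[1, ] - nm$absorbance[2, ])), 1e-12)
  expect_lt(max(abs(nm$absorbance[1, ] - nm$absorbance[3, ])), 1e-12)
  # idempotence
  expect_equal(normalize_to_band(nm)$absorbance, nm$absorbance,
               tolerance = 1e-12)
})

test_that("normalisation names the offending spectrum", {
  axis <- seq(1600, 1700, 4)
  ds <- spectral_dataset(matrix(-1, 1, length(axis)), axis,
                         "bad_one", "case", 1)
  expect_error(normalize_to_band(ds), "bad_one")
})

test_that("mean-centring uses the training mean only", {
  fx <- small_strong_fixture()
  train <- subset_spectra(fx$pp, fx$split$train)
  ctr <- mean_center(train)
  centred_train <- apply_centering(ctr, train)
  expect_lt(max(abs(colMeans(centred_train$absorbance))), 1e-12)

  one <- subset_spectra(train, 1)
  ctr1 <- mean_center(one)
  expect_equal(apply_centering(ctr1, one)$absorbance,
               matrix(0, 1, length(one$axis)))

  # held-out column means shift by exactly (held-out mean - train mean)
  held <- subset_spectra(fx$pp, fx$split$test)
  expect_equal(colMeans(apply_centering(ctr, held)$absorbance),
               colMeans(held$absorbance) - colMeans(train$absorbance),
               tolerance = 1e-12)

  other_axis <- tiny_dataset()
  expect_error(apply_centering(ctr, other_axis), "axis mismatch")
})

test_that("the full chain preserves spectrum count and metadata", {
  ds <- generate_cohort(cohort_config(n_per_class = 4, seed = 8))
  pp <- suppressWarnings(preprocess(ds))
  expect_equal(n_spectra(pp), n_spectra(ds))
  expect_identical(pp$sample_id, ds$sample_id)
  expect_identical(pp$class_label, ds$class_label)
  expect_identical(pp$replicate, ds$replicate)
  expect_equal(range(pp$axis), c(900, 1800))
})
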