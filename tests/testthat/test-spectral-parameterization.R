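test_that("aperiodic fit recovers exact power laws to high precision", {
  sp <- make_synthetic_spectrum(1.0, -1.2)
  fit <- fit_aperiodic(sp)
  expect_equal(fit$offset, 1.0, tolerance = 1e-6)
  expect_equal(fit$slope, -1.2, tolerance = 1e-6)

  flat <- make_synthetic_spectrum(log10(3.7), 0)
  fitf <- fit_aperiodic(flat)
  expect_equal(fitf$slope, 0, tolerance = 1e-9)
  expect_equal(fitf$offset, log10(3.7), tolerance = 1e-9)

  expect_error(fit_aperiodic(sp, fit_range = c(3, 4.5)), "fewer than 5")
  sp_bad <- sp
  sp_bad$power[10] <- 0
  expect_error(fit_aperiodic(sp_bad), "non-positive")
})

test_that("aperiodic fit ignores an oscillatory peak", {
  sp <- make_synthetic_spectrum(1.0, -1.0,
                                peaks = list(list(f0 = 10, height = 0.6,
                                                  sd = 1)))
  fit <- fit_aperiodic(sp)
  # oracle: OLS on the peak-free bins known from the generator
  sel <- sp$frequency >= 3 & sp$frequency <= 45 &
    abs(sp$frequency - 10) > 4
  ols <- stats::lm(log10(power) ~ log10(frequency), data = sp[sel, ])
  expect_equal(fit$offset, unname(coef(ols)[1]), tolerance = 0.05)
  expect_equal(fit$slope, unname(coef(ols)[2]), tolerance = 0.05)
  expect_equal(fit$offset, 1.0, tolerance = 0.05)
  expect_equal(fit$slope, -1.0, tolerance = 0.05)
})

test_that("flattening leaves the injected peak and absorbs offsets", {
  sp <- make_synthetic_spectrum(1.0, -1.2)
  flat <- flatten_spectrum(sp, fit_aperiodic(sp))
  expect_lt(max(abs(flat$residual)), 1e-6)

  spk <- make_synthetic_spectrum(0.5, -1.0,
                                 peaks = list(list(f0 = 10, height = 0.4,
                                                   sd = 1)))
  flatk <- flatten_spectrum(spk, fit_aperiodic(spk))
  truth <- 0.4 * exp(-(flatk$frequency - 10)^2 / 2)
  expect_lt(max(abs(flatk$residual - truth)), 0.05)

  sp2 <- spk
  sp2$power <- spk$power * 10^0.7          # constant in log10
  flat2 <- flatten_spectrum(sp2, fit_aperiodic(sp2))
  expect_equal(flat2$residual, flatk$residual, tolerance = 1e-9)

  wrong_grid <- make_synthetic_spectrum(1, -1, freq = seq(1, 50, 0.25))
  expect_error(flatten_spectrum(wrong_grid, fit_aperiodic(sp)), "grid")
})

test_that("peak detection finds bumps at bin resolution", {
  sp1 <- make_synthetic_spectrum(0, -1,
                                 peaks = list(list(f0 = 10, height = 0.5,
                                                   sd = 1)))
  pk1 <- detect_peaks(flatten_spectrum(sp1, fit_aperiodic(sp1)), sp1)
  expect_identical(nrow(pk1), 1L)
  expect_equal(pk1$frequency, 10)

  mono <- tibble::tibble(frequency = seq(3, 45, 0.5))
  mono_flat <- tibble::tibble(frequency = mono$frequency,
                              residual = -0.01 * mono$frequency)
  sp_mono <- tibble::tibble(frequency = mono$frequency, power = 1)
  expect_identical(nrow(detect_peaks(mono_flat, sp_mono)), 0L)

  sp2 <- make_synthetic_spectrum(0, -1,
                                 peaks = list(
                                   list(f0 = 6, height = 0.3, sd = 0.8),
                                   list(f0 = 10, height = 0.5, sd = 1)))
  pk2 <- detect_peaks(flatten_spectrum(sp2, fit_aperiodic(sp2)), sp2)
  expect_identical(nrow(pk2), 2L)
  expect_true(all(abs(sort(pk2$frequency) - c(6, 10)) <= 0.5))
})

test_that("raising the prominence threshold never adds peaks", {
  set.seed(8)
  for (rep in 1:5) {
    sp <- make_synthetic_spectrum(0, -1, noise_sd = 0.1,
                                  peaks = list(list(f0 = runif(1, 5, 30),
                                                    height = 0.5, sd = 1)))
    flat <- flatten_spectrum(sp, fit_aperiodic(sp))
    n_prev <- Inf
    for (prom in c(0.02, 0.05, 0.1, 0.2)) {
      n_now <- nrow(detect_peaks(flat, sp, min_prominence = prom))
      expect_lte(n_now, n_prev)
      n_prev <- n_now
    }
  }
})

test_that("dominant peak is judged on original power, ties to low freq", {
  # steep 1/f: the 6 Hz peak has more original power although the 10 Hz
  # peak has larger corrected amplitude
  sp <- make_synthetic_spectrum(1.5, -2.0,
                                peaks = list(
                                  list(f0 = 6, height = 0.3, sd = 0.8),
                                  list(f0 = 10, height = 0.5, sd = 0.8)))
  pk <- detect_peaks(flatten_spectrum(sp, fit_aperiodic(sp)), sp)
  expect_identical(nrow(pk), 2L)
  i6 <- which.min(abs(pk$frequency - 6))
  i10 <- which.min(abs(pk$frequency - 10))
  expect_gt(pk$original_power[i6], pk$original_power[i10])
  expect_lt(pk$amplitude[i6], pk$amplitude[i10])
  expect_equal(dominant_peak(pk), pk$frequency[i6])

  one <- pk[i10, ]
  expect_equal(dominant_peak(one), pk$frequency[i10])
  expect_identical(dominant_peak(pk[0, ]), NA_real_)
})

test_that("band-specific peaks use corrected amplitude within the band", {
  peaks <- tibble::tibble(frequency = c(6, 10, 20),
                          amplitude = c(0.3, 0.5, 0.2),
                          original_power = c(3, 2, 1))
  expect_equal(band_specific_peak(peaks, c(8.5, 13)), 10)
  expect_identical(band_specific_peak(peaks, c(27.5, 34)), NA_real_)
  two <- tibble::tibble(frequency = c(9, 11), amplitude = c(0.3, 0.5),
                        original_power = c(1, 1))
  expect_equal(band_specific_peak(two, c(8.5, 13)), 11)
  bands <- default_bands()
  expect_equal(band_specific_peak(peaks, bands[bands$label == "alpha", ]),
               10)
})

test_that("default bands carry the classical edges", {
  b <- default_bands()
  expect_identical(b$label, c("theta", "alpha", "lowbeta", "highbeta"))
  expect_equal(b$f_low, c(4, 8.5, 15, 27.5))
  expect_equal(b$f_high, c(7.5, 13, 25, 34))
})

test_that("peak histogram splits two clusters near the mixture minimum", {
  set.seed(9)
  pf <- c(rnorm(2500, 5, 0.6), rnorm(2500, 10, 0.6))
  bands <- peak_histogram_bands(pf)
  expect_identical(nrow(bands), 2L)
  boundary <- bands$f_high[1]
  expect_lt(abs(boundary - 7.5), 1)

  single <- peak_histogram_bands(rnorm(1000, 10, 0.8))
  expect_identical(nrow(single), 1L)
  expect_lt(single$f_low, 9)
  expect_gt(single$f_high, 11)

  expect_error(peak_histogram_bands(rnorm(50, 10, 1)), "100")
})

test_that("rescaling a spectrum shifts only the offset", {
  set.seed(10)
  sp <- make_synthetic_spectrum(0.3, -1.1, noise_sd = 0.02,
                                peaks = list(list(f0 = 11, height = 0.6,
                                                  sd = 1)))
  sp_scaled <- sp
  sp_scaled$power <- sp$power * 50
  f1 <- fit_aperiodic(sp)
  f2 <- fit_aperiodic(sp_scaled)
  expect_equal(f2$slope, f1$slope, tolerance = 1e-9)
  expect_equal(f2$offset - f1$offset, log10(50), tolerance = 1e-9)
  p1 <- detect_peaks(flatten_spectrum(sp, f1), sp)
  p2 <- detect_peaks(flatten_spectrum(sp_scaled, f2), sp_scaled)
  expect_identical(p1$frequency, p2$frequency)
  expect_identical(dominant_peak(p1), dominant_peak(p2))
})

test_that("parameterize_spectra yields one row per spectrum with bands", {
  set.seed(11)
  fs <- 300
  mk <- function(roi, f0) {
    x <- bandlimited_oscillation(fs * 30, fs, f0, 1) * 1.2 +
      colored_noise(fs * 30, fs, -1, -1.2)
    sp <- pooled_roi_spectrum(segment_epochs(matrix(x, nrow = 1), 2, fs))
    tibble::tibble(participant = "s1", hemisphere = "L", roi_id = roi,
                   frequency = sp$frequency, power = sp$power)
  }
  spectra <- dplyr::bind_rows(mk("A", 9.5), mk("B", 11.5))
  feat <- parameterize_spectra(spectra)
  expect_identical(nrow(feat), 2L)
  expect_true(all(c("pf", "aperiodic_offset", "aperiodic_slope",
                    "pf_theta", "pf_alpha") %in% names(feat)))
  expect_lte(abs(feat$pf[feat$roi_id == "A"] - 9.5), 1)
  expect_lte(abs(feat$pf[feat$roi_id == "B"] - 11.5), 1)
  expect_identical(feat$pf, feat$pf_alpha)
})
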