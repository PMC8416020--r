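test_that("read_spectrum round-trips files, sorts, and rejects bad tables", {
  tr <- spectrum_truth(noise_sd = 0.01, seed = 7)
  s <- gen_spectrum(tr)$spectrum
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(s, f)
  s2 <- read_spectrum(f, condition = "apo", probe = "5.58", replicate = 2)
  expect_length(s2$wavelengths, 261L)
  expect_equal(s2$wavelengths, s$wavelengths)
  expect_equal(s2$intensities, s$intensities, tolerance = 1e-12)
  expect_identical(s2$condition, "apo")

  # descending table reads to the same ascending spectrum
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(wavelength = rev(s$wavelengths),
                              intensity = rev(s$intensities)),
                   f2, row.names = FALSE)
  s3 <- read_spectrum(f2)
  expect_equal(s3$wavelengths, s$wavelengths)
  expect_equal(s3$intensities, s$intensities)

  # tab-separated, headerless
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(s$wavelengths, s$intensities, sep = "\t"), f3)
  expect_equal(read_spectrum(f3)$intensities, s$intensities)

  # duplicated wavelength
  f4 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(w = c(340, 340, 341:360), i = runif(22)),
                   f4, row.names = FALSE)
  expect_error(read_spectrum(f4), "duplicated")

  # too few points
  f5 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(w = 1:5, i = 1:5), f5, row.names = FALSE)
  expect_error(read_spectrum(f5), "at least 10")

  # non-numeric rows
  f6 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength,intensity", paste(340:360, "x", sep = ",")), f6)
  expect_error(read_spectrum(f6), "non-numeric|parse")
})

test_that("normalize_spectrum scales to unit peak and is idempotent", {
  s <- spectrum(seq(340, 600, 20), rep(5, 14))
  n1 <- normalize_spectrum(s)
  expect_true(all(n1$intensities == 1))
  expect_equal(normalize_spectrum(n1), n1)
  z <- spectrum(seq(340, 600, 20), rep(0, 14))
  expect_error(normalize_spectrum(z), "all-zero")
})

test_that("evaluate_band_model follows the peak-height convention and is linear", {
  wl <- seq(340, 600, 1)
  b0 <- lapply(c("neutral", "anionic", "tautomer"), function(sp)
    band_component(sp, 450, 30, 0))
  expect_equal(evaluate_band_model(b0, 0, wl), rep(0, length(wl)))

  b1 <- band_component("anionic", 450, 25, 0.8)
  y1 <- evaluate_band_model(list(b1), baseline = 0.05, wavelengths = wl)
  expect_equal(y1[wl == 450], 0.8 + 0.05)

  b2 <- band_component("tautomer", 520, 35, 0.4)
  y_sum <- evaluate_band_model(list(b1, b2), 0, wl)
  expect_equal(y_sum,
               evaluate_band_model(list(b1), 0, wl) +
                 evaluate_band_model(list(b2), 0, wl))

  expect_error(evaluate_band_model(list(b1), 0, numeric(0)), "empty")
  expect_error(evaluate_band_model(list(b1, b1), 0, wl), "duplicate")

  # lognormal band also peaks at its centre with its amplitude
  bl <- band_component("anionic", 450, 25, 0.6, shape = "lognormal")
  yl <- evaluate_band_model(list(bl), 0, wl)
  expect_equal(yl[wl == 450], 0.6)
  expect_equal(max(yl), 0.6)
})

test_that("noiseless synthetic spectra are recovered essentially exactly", {
  tr <- spectrum_truth(c(neutral = 0.35, anionic = 0.25, tautomer = 0.40))
  fit <- fit_band_model(gen_spectrum(tr)$spectrum)
  expect_lt(max(abs(fit$fractional_areas - tr$fractions)), 1e-6)
  expect_gte(fit$r_squared, 1 - 1e-9)
  expect_equal(fit$H, tr$H_true, tolerance = 1e-6)
  expect_equal(sum(fit$fractional_areas), 1, tolerance = 1e-9)
})

test_that("a neutral-only spectrum yields vanishing anionic/tautomer areas", {
  tr <- spectrum_truth(c(neutral = 1, anionic = 0, tautomer = 0))
  fit <- fit_band_model(gen_spectrum(tr)$spectrum)
  expect_lt(fit$fractional_areas[["anionic"]], 1e-6)
  expect_lt(fit$fractional_areas[["tautomer"]], 1e-6)
  expect_lt(fit$H, 1e-6)
})

test_that("fitting is invariant to overall intensity scaling", {
  tr <- spectrum_truth(c(neutral = 0.5, anionic = 0.2, tautomer = 0.3),
                       noise_sd = 0.01, seed = 11)
  s <- gen_spectrum(tr)$spectrum
  s_scaled <- s
  s_scaled$intensities <- s$intensities * 73.2
  f1 <- fit_band_model(s)
  f2 <- fit_band_model(s_scaled)
  expect_lt(max(abs(f1$fractional_areas - f2$fractional_areas)), 1e-9)
})

test_that("degenerate spectra are rejected by the fitter", {
  z <- spectrum(seq(340, 600, 20), rep(0, 14))
  expect_error(fit_band_model(z), "all-zero")
  s <- gen_spectrum(spectrum_truth())$spectrum
  expect_error(fit_band_model(s, init = default_bands()[1:2]),
               "exactly the .* species|species")
})

test_that("hydration_parameter is the anionic + tautomer area fraction", {
  fake <- function(frac) {
    structure(list(fractional_areas = frac, areas = frac,
                   h_mode = "fractional"), class = "deconvolution")
  }
  expect_equal(hydration_parameter(
    fake(c(neutral = 1, anionic = 0, tautomer = 0))), 0)
  expect_equal(hydration_parameter(
    fake(c(neutral = 0, anionic = 0.4, tautomer = 0.6))), 1)
  expect_equal(hydration_parameter(
    fake(c(neutral = 0.4, anionic = 0.4, tautomer = 0.2))), 0.6)
  expect_error(hydration_parameter(fake(c(neutral = 0.5, anionic = 0.5))),
               "missing species")
})

test_that("estimated H tracks the injected truth monotonically (noiseless ladder)", {
  h_grid <- seq(0, 1, length.out = 21)
  h_hat <- vapply(h_grid, function(h) {
    tr <- spectrum_truth(c(neutral = 1 - h, anionic = 0.5 * h,
                           tautomer = 0.5 * h))
    fit_band_model(gen_spectrum(tr)$spectrum)$H
  }, numeric(1))
  expect_true(all(h_hat >= 0 & h_hat <= 1))
  expect_gt(suppressWarnings(cor(h_grid, h_hat, method = "spearman")), 0.99)
})

test_that("H is recovered to within 0.02 under 1% peak noise (spot check)", {
  errs <- vapply(1:10, function(seed) {
    tr <- spectrum_truth(c(neutral = 0.4, anionic = 0.25, tautomer = 0.35),
                         noise_sd = 0.01, seed = seed)
    abs(fit_band_model(gen_spectrum(tr)$spectrum)$H - 0.6)
  }, numeric(1))
  expect_lt(mean(errs), 0.02)
})

test_that("lognormal band shape round-trips through the fitter", {
  tr <- spectrum_truth(c(neutral = 0.3, anionic = 0.3, tautomer = 0.4),
                       shape = "lognormal")
  fit <- fit_band_model(gen_spectrum(tr)$spectrum,
                        init = default_bands("lognormal"))
  expect_lt(max(abs(fit$fractional_areas - tr$fractions)), 1e-5)
  expect_gte(fit$r_squared, 1 - 1e-7)
})
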