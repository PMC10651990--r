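test_that("Welch PSD is density-normalized with the stated resolution", {
  set.seed(1)
  x <- rnorm(512 * 60)
  ps <- welch_psd(x, 512)
  expect_equal(diff(ps$freqs[1:2]), 0.5)
  expect_equal(sum(ps$power) * 0.5, 1, tolerance = 0.05)

  s <- sin(2 * pi * 10 * (0:(512 * 10 - 1)) / 512)
  ps2 <- welch_psd(s, 512, segment_s = 2)
  expect_equal(ps2$freqs[which.max(ps2$power)], 10)

  expect_error(welch_psd(rnorm(100), 512, segment_s = 2),
               class = "acinet_invalid_argument")
  expect_error(welch_psd(rnorm(100), 512, overlap_frac = 1),
               class = "acinet_invalid_argument")
})

test_that("aperiodic fit recovers exact power laws and resists peaks", {
  f <- seq(1, 80, by = 0.5)
  ps <- list(freqs = f, power = 10^1.5 * f^-2)
  ap <- fit_aperiodic(ps)
  expect_equal(ap$offset, 1.5, tolerance = 1e-8)
  expect_equal(ap$exponent, 2, tolerance = 1e-8)
  expect_identical(ap$knee, 0)

  # an added Gaussian bump must not drag the robust fit
  bump <- 10^(log10(ps$power) + 0.8 * exp(-(f - 10)^2 / (2 * 4)))
  ap2 <- fit_aperiodic(list(freqs = f, power = bump))
  expect_lt(abs(ap2$exponent - 2), 0.1)

  flat <- fit_aperiodic(list(freqs = f, power = rep(2, length(f))))
  expect_lt(abs(flat$exponent), 1e-8)

  expect_error(fit_aperiodic(list(freqs = 1:3, power = rep(1, 3))),
               class = "acinet_fit_error")
})

test_that("peak extraction is sensitive to real peaks and quiet on noise", {
  f <- seq(1, 80, by = 0.5)
  hits <- vapply(1:50, function(s) {
    set.seed(s)
    flat <- 0.6 * exp(-(f - 10)^2 / (2 * 4)) + rnorm(length(f), sd = 0.05)
    pk <- fit_peaks(f, flat)
    nrow(pk) >= 1 && abs(pk$center[1] - 10) <= 0.5
  }, TRUE)
  expect_gte(mean(hits), 0.95)

  zero <- vapply(1:30, function(s) {
    set.seed(100 + s)
    nrow(fit_peaks(f, rnorm(length(f), sd = 0.05))) == 0
  }, TRUE)
  expect_gte(mean(zero), 0.9)

  # the peak cap is enforced and keeps the largest peaks
  flat4 <- 0.9 * exp(-(f - 8)^2 / 2) + 0.8 * exp(-(f - 25)^2 / 2) +
    0.7 * exp(-(f - 45)^2 / 2) + 0.6 * exp(-(f - 65)^2 / 2)
  pk4 <- fit_peaks(f, flat4, max_n = 3)
  expect_identical(nrow(pk4), 3L)
  expect_true(all(abs(sort(pk4$center) - c(8, 25, 45)) < 1))
  # width limits respected
  expect_true(all(pk4$width >= 0.25 - 1e-9 & pk4$width <= 6 + 1e-9))
})

test_that("full parameterization recovers model-generated spectra", {
  truth <- structure(list(offset = 1, knee = 0, exponent = 1,
                          peaks = data.frame(amplitude = 0.5, center = 10,
                                             width = 2),
                          fit_range = c(1, 80), mode = "fixed"),
                     class = "spectrum_model")
  f <- seq(1, 80, by = 0.5)
  ps <- model_spectrum(truth, f)
  m <- parameterize_spectrum(ps)
  expect_equal(m$offset, 1, tolerance = 0.05)
  expect_equal(m$exponent, 1, tolerance = 0.1)
  expect_identical(nrow(m$peaks), 1L)
  expect_equal(m$peaks$amplitude, 0.5, tolerance = 0.1)
  expect_equal(m$peaks$center, 10, tolerance = 0.5)
  expect_equal(m$peaks$width, 2, tolerance = 0.5)
  expect_gt(m$gof$r_squared, 0.99)

  # forward model basics
  unit <- structure(list(offset = 0, knee = 0, exponent = 0,
                         peaks = data.frame(amplitude = numeric(0),
                                            center = numeric(0),
                                            width = numeric(0)),
                         fit_range = c(1, 80), mode = "fixed"),
                    class = "spectrum_model")
  expect_equal(model_spectrum(unit, f)$power, rep(1, length(f)))
  # peak contribution at its center equals the amplitude in log10 units
  expect_equal(log10(model_spectrum(truth, 10)$power) -
                 (1 - 1 * log10(10)), 0.5, tolerance = 1e-10)
})

test_that("white-noise signals parameterize to a near-zero exponent", {
  chis <- vapply(1:10, function(s) {
    x <- gen_aperiodic_series(512 * 20, 512, 0, seed = 300 + s)
    parameterize_spectrum(welch_psd(x, 512))$exponent
  }, 0)
  expect_lt(max(abs(chis)), 0.15)
})

test_that("scale equivariance: gain moves the offset, not exponent or peaks", {
  x <- gen_aperiodic_series(512 * 30, 512, 1.5, seed = 12) +
    gen_oscillation(512 * 30, 512, 10, 2, 1, seed = 13)
  m1 <- parameterize_spectrum(welch_psd(x, 512))
  m2 <- parameterize_spectrum(welch_psd(20 * x, 512))
  expect_equal(m2$offset - m1$offset, 2 * log10(20), tolerance = 0.01)
  expect_equal(m2$exponent, m1$exponent, tolerance = 0.01)
  expect_equal(m2$peaks$center[1], m1$peaks$center[1], tolerance = 0.01)
})

test_that("the E:I index is minus the exponent and ordinally monotone", {
  mk <- function(chi) structure(list(offset = 0, knee = 0, exponent = chi,
                                     peaks = data.frame(), fit_range = c(1, 80),
                                     mode = "fixed"), class = "spectrum_model")
  expect_identical(ei_index(mk(0)), 0)
  expect_gt(ei_index(mk(1)), ei_index(mk(2)))
  chis <- c(0.5, 1, 1.5, 2)
  eis <- vapply(chis, function(ch) ei_index(mk(ch)), 0)
  expect_true(all(diff(eis) < 0))
})
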