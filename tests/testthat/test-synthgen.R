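test_that("aperiodic generator is seeded, normalized and spectrally faithful", {
  x <- gen_aperiodic_series(4096, 512, 2, seed = 7)
  expect_identical(x, gen_aperiodic_series(4096, 512, 2, seed = 7))
  expect_lt(abs(mean(x)), 1e-10)
  expect_equal(sd(x), 1, tolerance = 1e-10)

  # white-noise limit: fitted exponent near zero
  w <- gen_aperiodic_series(4096, 512, 0, seed = 1)
  m <- fit_aperiodic(welch_psd(w, 512))
  expect_lt(abs(m$exponent), 0.1)

  # long-run exponent recovery against the independent periodogram oracle
  x2 <- gen_aperiodic_series(2^16, 512, 2, seed = 0)
  expect_lt(abs(periodogram_exponent(x2, 512) - 2), 0.15)

  expect_error(gen_aperiodic_series(0, 512, 1), class = "acinet_invalid_argument")
  expect_error(gen_aperiodic_series(100, 512, -1), class = "acinet_invalid_argument")
})

test_that("oscillation generator hits its band and amplitude", {
  y <- gen_oscillation(512 * 20, 512, center = 10, bandwidth = 2,
                       amplitude = 1.3, seed = 3)
  expect_equal(sqrt(mean(y^2)), 1.3, tolerance = 1e-8)

  # dominant averaged-periodogram peak within the alpha band over seeds
  peaks <- vapply(1:12, function(s) {
    ps <- welch_psd(gen_oscillation(512 * 8, 512, 10, 2, 1, seed = s), 512)
    ps$freqs[which.max(ps$power)]
  }, 0)
  expect_true(all(peaks >= 8 & peaks < 13))

  expect_identical(gen_oscillation(1000, 512, 10, 2, 0, seed = 1), numeric(1000))
  expect_error(gen_oscillation(1000, 512, 300, 2, 1), class = "acinet_invalid_argument")
})

test_that("scheduled exponents are recovered per period from the SOZ channel", {
  scen <- gen_seizure_scenario(sim_config(seed = 4))
  seg <- segment_periods(scen$annotation, 512)
  sched <- scen$truth$exponent_schedule$soz
  for (p in c("IID", "PI")) {  # pre-onset periods carry no oscillation
    r <- seg[seg$period == p, ]
    x <- scen$recording$data[1, (r$start + 1):r$end] # nolint
    m <- parameterize_spectrum(welch_psd(x, 512))
    expect_lt(abs(m$exponent - sched[[p]]), 0.2)
  }
  # onset flattening visible on the SOZ channel
  so <- seg[seg$period == "SO", ]
  iid <- seg[seg$period == "IID", ]
  chi_so <- parameterize_spectrum(
    welch_psd(scen$recording$data[1, (so$start + 1):so$end], 512))$exponent
  chi_iid <- parameterize_spectrum(
    welch_psd(scen$recording$data[1, (iid$start + 1):iid$end], 512))$exponent
  expect_lt(chi_so, chi_iid)
})

test_that("coupled pair honours identity coupling and direction bookkeeping", {
  # c = 1, identity, zero lag, no pathway filtering: follower equals the
  # (scaled) driver exactly
  sim <- gen_coupled_pair(sim_config(
    fs = 512, duration_s = 10, seed = 5, onset_time_s = NA,
    coupling_schedule = 1, lag_s = 0, coupling_fn = "identity",
    coupling_lowpass_hz = NA,
    exponent_schedule = list(soz = 1.5, nonsoz = 1.5)))
  x <- sim$recording$data[1, ]
  y <- sim$recording$data[2, ]
  expect_gt(nonlinear_regression_h2(x, y), 0.99)

  sim2 <- gen_coupled_pair(sim_config(seed = 1, soz_channel = 2))
  expect_identical(sim2$truth$true_direction, -1L)
  expect_identical(sim2$truth$soz_channel, "ch2")
  expect_identical(sim2$recording$soz_flags[["ch2"]], "SOZ")

  # determinism of the full scenario
  a <- gen_seizure_scenario(sim_config(seed = 11))
  b <- gen_seizure_scenario(sim_config(seed = 11))
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(round(a$annotation$onset_s * 512), 70 * 512)
})

test_that("zero-coupling pairs are statistically independent", {
  h2s <- vapply(1:10, function(s) {
    sim <- gen_coupled_pair(sim_config(
      fs = 512, duration_s = 4, seed = s, onset_time_s = NA,
      coupling_schedule = 0, exponent_schedule = list(soz = 1, nonsoz = 1)))
    nonlinear_regression_h2(sim$recording$data[1, ], sim$recording$data[2, ])
  }, 0)
  expect_lt(mean(h2s), 0.1)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(coupling_schedule = 1.5), class = "acinet_invalid_argument")
  expect_error(sim_config(lag_s = 0.2), class = "acinet_invalid_argument")
  expect_error(sim_config(onset_time_s = 5), class = "acinet_invalid_argument")
  expect_error(sim_config(onset_peak = c(300, 2, 1)), class = "acinet_invalid_argument")
  expect_error(gen_seizure_scenario(sim_config(onset_time_s = NA)),
               class = "acinet_invalid_argument")
})
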