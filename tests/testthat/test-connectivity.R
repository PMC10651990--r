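test_that("band table partitions 0.5-80 Hz and the filter is band-selective", {
  bt <- band_table()
  expect_identical(bt$lo[-1], bt$hi[-nrow(bt)])  # contiguous

  fs <- 512
  t <- (0:(fs * 10 - 1)) / fs
  s10 <- sin(2 * pi * 10 * t)
  inband <- bandpass(s10, fs, "alpha")
  mid <- (fs * 2):(fs * 8)  # avoid filter edge transients
  expect_equal(sqrt(mean(inband[mid]^2)), sqrt(0.5), tolerance = 0.05)
  stopband <- bandpass(s10, fs, "gamma1")
  expect_lt(sqrt(mean(stopband[mid]^2)), 0.05 * sqrt(0.5))

  # white noise through alpha: spectral mass concentrated around the band
  set.seed(2)
  wn <- bandpass(rnorm(fs * 30), fs, "alpha")
  ps <- welch_psd(wn, fs)
  inside <- ps$freqs >= 6 & ps$freqs <= 15
  expect_lt(sum(ps$power[!inside]) / sum(ps$power), 0.1)

  expect_error(bandpass(s10, 100, c(30, 60)), class = "acinet_invalid_argument")
})

test_that("h2 captures identity, quadratic and null relations correctly", {
  set.seed(5)
  x <- runif(5000, -1, 1)
  expect_gt(nonlinear_regression_h2(x, x, nbins = 8), 0.99)

  y <- x^2
  expect_gte(nonlinear_regression_h2(x, y, nbins = 8), 0.9)
  expect_lte(cor(x, y)^2, 0.05)

  # independent pair vs its own permutation null
  set.seed(6)
  a <- rnorm(1024); b <- rnorm(1024)
  h2_obs <- nonlinear_regression_h2(a, b, nbins = 8)
  null <- vapply(1:1000, function(i) {
    nonlinear_regression_h2(a, sample(b), nbins = 8)
  }, 0)
  expect_lt(h2_obs, quantile(null, 0.95))
  expect_lt(quantile(null, 0.95), 0.1)

  expect_identical(nonlinear_regression_h2(rep(1, 100), rnorm(100), nbins = 4), 0)
  expect_error(nonlinear_regression_h2(rnorm(100), rep(2, 100), nbins = 4),
               class = "acinet_undefined_variance")
  expect_error(nonlinear_regression_h2(rnorm(50), rnorm(50), nbins = 16),
               class = "acinet_invalid_argument")
})

test_that("h2 at the optimal lag matches squared correlation for linear pairs", {
  set.seed(7)
  n <- 1e4
  for (rho in c(0.3, 0.6, 0.9)) {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    expect_equal(nonlinear_regression_h2(x, y), rho^2, tolerance = 0.05)
  }
})

test_that("lag scan recovers pure delays and honours the tie rule", {
  fs <- 512
  x <- gen_aperiodic_series(fs * 3, fs, 1.5, seed = 21)
  d <- round(0.02 * fs)  # 20 ms
  y <- c(numeric(d), x[1:(fs * 3 - d)])
  n <- fs * 2
  sc <- h2_lag_scan(x[1:n], y[1:n], fs)
  expect_equal(sc$tau, d / fs, tolerance = 1 / fs)
  expect_gt(sc$h2, 0.99)
  # the reverse direction sees the negative lag
  rv <- h2_lag_scan(y[1:n], x[1:n], fs)
  expect_equal(rv$tau, -d / fs, tolerance = 1 / fs)

  # symmetric inputs: tau = 0 by the tie rule
  sym <- h2_lag_scan(x[1:n], x[1:n], fs)
  expect_identical(sym$tau, 0)

  expect_error(h2_lag_scan(x[1:200], y[1:200], fs, max_lag_s = 0.3),
               class = "acinet_invalid_argument")
})

test_that("the direction index follows its truth table and antisymmetry", {
  expect_identical(direction_index(0.3, 0.02), 1)
  expect_identical(direction_index(-0.3, -0.02), -1)
  expect_identical(direction_index(0.3, -0.02), 0)
  expect_identical(direction_index(-0.3, 0.02), 0)
  expect_identical(direction_index(0, 0.02), 0.5)
  expect_identical(direction_index(0.3, 0), 0.5)
  expect_identical(direction_index(0, 0), 0)
  expect_error(direction_index(NaN, 1), class = "acinet_invalid_argument")

  set.seed(8)
  dh <- rnorm(1000); dt <- rnorm(1000)
  D <- direction_index(dh, dt)
  expect_true(all(D %in% c(-1, -0.5, 0, 0.5, 1)))
  expect_identical(direction_index(-dh, -dt), -D)
})

test_that("sliding windows have the expected count and bounded outputs", {
  sim <- onset_state_epoch(31)
  w <- sliding_h2(sim$recording$data[1, ], sim$recording$data[2, ], 512)
  expect_identical(nrow(w), 9L)  # 10-s segment, 2-s windows, 1-s steps
  expect_true(all(w$h2_xy >= 0 & w$h2_xy <= 1))
  expect_true(all(w$h2_yx >= 0 & w$h2_yx <= 1))
  expect_true(all(abs(w$tau_xy) <= 0.1 + 1e-12))
  expect_true(all(w$D %in% c(-1, -0.5, 0, 0.5, 1)))

  # antisymmetry under swapping the channel roles
  w2 <- sliding_h2(sim$recording$data[2, ], sim$recording$data[1, ], 512)
  expect_equal(w2$D, -w$D)
  expect_equal(w2$delta_h2, -w$delta_h2)
})

test_that("quadratically coupled pairs yield the true lag and direction", {
  taus <- vapply(1:8, function(s) {
    sim <- onset_state_epoch(40 + s)
    w <- sliding_h2(sim$recording$data[1, ], sim$recording$data[2, ], 512)
    stats::median(w$tau_xy)
  }, 0)
  expect_true(all(abs(taus - 0.02) <= 1 / 512))

  meanD <- vapply(1:8, function(s) {
    sim <- onset_state_epoch(60 + s)
    mean(sliding_h2(sim$recording$data[1, ], sim$recording$data[2, ], 512)$D)
  }, 0)
  expect_true(all(meanD > 0))
})

test_that("band-specific coupling is seen in its band and not elsewhere", {
  fs <- 512
  n <- fs * 12
  osc <- gen_oscillation(n, fs, 10, 2, 1.5, seed = 71)
  d <- round(0.02 * fs)
  x <- gen_aperiodic_series(n, fs, 1.2, seed = 72) + osc
  y <- gen_aperiodic_series(n, fs, 1.2, seed = 73) +
    c(numeric(d), osc[1:(n - d)])
  xa <- bandpass(x, fs, "alpha"); ya <- bandpass(y, fs, "alpha")
  xg <- bandpass(x, fs, "gamma1"); yg <- bandpass(y, fs, "gamma1")
  idx <- (fs + 1):(fs * 11)  # drop filter edges
  h2_alpha <- mean(sliding_h2(xa[idx], ya[idx], fs)$h2_xy)
  h2_gamma <- mean(sliding_h2(xg[idx], yg[idx], fs)$h2_xy)
  expect_gt(h2_alpha, 0.5)
  expect_lt(h2_gamma, 0.3)
})

test_that("period aggregation orders onset above interictal connectivity", {
  rep <- default_report()
  p <- rep$periods
  expect_identical(p$period, c("IID", "PI", "SO", "SP"))
  expect_identical(p$n_windows, rep(9L, 4))
  expect_gt(p$mean_h2[p$period == "SO"], p$mean_h2[p$period == "IID"])
  expect_true(all(p$mean_h2 >= 0 & p$mean_h2 <= 1))
  expect_true(all(abs(p$mean_D) <= 1))
})
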