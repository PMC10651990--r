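# Independent oracles and shared fixtures for the test suite.

# Brute-force Benjamini-Hochberg step-up, written directly from the
# definition: adj_i = min over j >= rank(i) of min(1, m * p_(j) / j).
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    adj_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

# Aperiodic exponent by plain log-log least squares on a raw averaged
# periodogram (rectangular window, non-overlapping segments): independent
# of welch_psd/fit_aperiodic.
periodogram_exponent <- function(x, fs, nseg = 32, fmin = 1, fmax = 80) {
  n <- length(x)
  nper <- floor(n / nseg)
  acc <- NULL
  for (s in seq_len(nseg)) {
    seg <- x[((s - 1) * nper + 1):(s * nper)]
    sp <- abs(stats::fft(seg - mean(seg)))^2
    acc <- if (is.null(acc)) sp else acc + sp
  }
  freqs <- (0:(nper - 1)) * fs / nper
  sel <- freqs >= fmin & freqs <= fmax
  fit <- stats::lm(log10(acc[sel]) ~ log10(freqs[sel]))
  -unname(stats::coef(fit)[2])
}

# The default seizure scenario report is reused by several tests; compute
# it once per test run.
default_report <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressWarnings(run_pipeline(list(sim = sim_config(seed = 0))))
    }
    cache
  }
})

# Stationary coupled epoch in the generator's seizure-onset state
# (c = 0.7, matched flattened backgrounds), used by the direction-recovery
# studies.
onset_state_epoch <- function(seed, c_strength = 0.7) {
  gen_coupled_pair(sim_config(
    fs = 512, duration_s = 10, seed = seed, onset_time_s = NA,
    coupling_schedule = c_strength,
    exponent_schedule = list(soz = 1.2, nonsoz = 1.2)
  ))
}
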