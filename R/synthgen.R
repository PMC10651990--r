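# Synthetic SEEG generator: 1/f^chi background, narrowband oscillations,
# lagged (possibly nonlinear) directional coupling with a per-period schedule,
# plus the ground truth needed to validate every downstream estimator.

#' Simulation configuration for a coupled SEEG channel pair
#'
#' Bundles and validates every knob of the generator. Schedules are named
#' vectors over the four analysis periods (`IID`, `PI`, `SO`, `SP`); a single
#' unnamed value is recycled to all periods (useful for stationary epochs).
#'
#' @param fs sampling rate in Hz (default 512).
#' @param duration_s total duration in seconds. Defaults to
#'   `onset_time_s + 20` so the propagation period fits exactly.
#' @param seed integer root seed; all component streams derive from it.
#' @param exponent_schedule list with elements `soz` and `nonsoz`, each a
#'   per-period aperiodic exponent chi (dimensionless). Defaults follow the
#'   seizure scenario: SOZ chi = (IID 2.0, PI 1.8, SO 1.2, SP 1.5), non-SOZ
#'   chi = (2.0, 1.9, 1.5, 1.6).
#' @param coupling_schedule per-period coupling strength c in \[0, 1\];
#'   default (IID 0.05, PI 0.15, SO 0.7, SP 0.4).
#' @param lag_s coupling delay in seconds, in \[0, 0.1) (default 0.02).
#' @param coupling_fn one of `"identity"`, `"quadratic"`, `"sigmoid"`.
#'   The default, quadratic (u^2 centred), produces a non-invertible
#'   driver-to-follower map that linear correlation cannot capture.
#' @param coupling_lowpass_hz zero-phase first-order low-pass cutoff on the
#'   coupled pathway (default 80 Hz; `NA` disables). Models the dendritic/
#'   synaptic filtering of propagated activity: without it a nonlinear
#'   transform injects broadband power into the follower and the follower's
#'   apparent 1/f exponent no longer reflects its scheduled value. The
#'   gentle first-order roll-off avoids putting a sharp spectral knee
#'   inside the analysis range, and zero-phase filtering leaves the
#'   coupling lag intact.
#' @param onset_peak numeric `c(center, bandwidth, amplitude)` of the ictal
#'   oscillation in Hz, Hz and RMS units relative to the unit-variance
#'   background (default 10 Hz, 3 Hz, 1.5).
#' @param onset_time_s seizure-onset time in seconds; must leave at least
#'   10 s before and 20 s after. Default `iid_offset_s + 10`. `NA` requests
#'   a stationary epoch with no onset: the interictal schedule values apply
#'   throughout and no ictal oscillation is injected (used for
#'   parameter-recovery studies on short epochs).
#' @param iid_offset_s gap between the end of the interictal window and
#'   onset (default 60; use 7200 to match a 2-hour clinical separation).
#' @param soz_channel which channel (1 or 2) plays the seizure-onset zone,
#'   i.e. drives the other (default 1).
#' @return An object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$coupling_schedule
sim_config <- function(fs = 512,
                       duration_s = NULL,
                       seed = 0L,
                       exponent_schedule = NULL,
                       coupling_schedule = NULL,
                       lag_s = 0.02,
                       coupling_fn = c("quadratic", "identity", "sigmoid"),
                       coupling_lowpass_hz = 80,
                       onset_peak = c(center = 10, bandwidth = 3, amplitude = 1.5),
                       onset_time_s = NULL,
                       iid_offset_s = 60,
                       soz_channel = 1L) {
  stopifnot_scalar_num(fs, "fs", positive = TRUE)
  coupling_fn <- match.arg(coupling_fn)
  if (is.null(onset_time_s)) onset_time_s <- iid_offset_s + 10
  stationary <- length(onset_time_s) == 1L && is.na(onset_time_s)
  if (is.null(duration_s)) {
    duration_s <- if (stationary) 10 else onset_time_s + 20
  }
  stopifnot_scalar_num(duration_s, "duration_s", positive = TRUE)
  if (!is.numeric(lag_s) || lag_s < 0 || lag_s >= 0.1) {
    abort("`lag_s` must lie in [0, 0.1) seconds", "acinet_invalid_argument")
  }
  if (!stationary) {
    stopifnot_scalar_num(onset_time_s, "onset_time_s", positive = TRUE)
    if (onset_time_s < 10 || duration_s - onset_time_s < 20) {
      abort("onset must leave >= 10 s before and >= 20 s after it",
            "acinet_invalid_argument")
    }
    # interictal window [onset - offset - 10, onset - offset) must start >= 0
    if (onset_time_s < iid_offset_s + 10) {
      abort("recording too short for the interictal window at this iid_offset_s",
            "acinet_invalid_argument")
    }
  }
  if (!soz_channel %in% c(1L, 2L)) {
    abort("`soz_channel` must be 1 or 2", "acinet_invalid_argument")
  }

  periods <- c("IID", "PI", "SO", "SP")
  expand <- function(x, default) {
    if (is.null(x)) x <- default
    if (length(x) == 1L && is.null(names(x))) x <- rep(x, 4L)
    if (is.null(names(x))) names(x) <- periods
    x <- x[periods]
    if (anyNA(x)) abort("schedule must name all of IID, PI, SO, SP",
                        "acinet_invalid_argument")
    x
  }
  if (is.null(exponent_schedule)) {
    exponent_schedule <- list(
      soz    = c(IID = 2.0, PI = 1.8, SO = 1.2, SP = 1.5),
      nonsoz = c(IID = 2.0, PI = 1.9, SO = 1.5, SP = 1.6)
    )
  }
  exponent_schedule$soz <- expand(exponent_schedule$soz, NULL)
  exponent_schedule$nonsoz <- expand(exponent_schedule$nonsoz, NULL)
  coupling_schedule <- expand(coupling_schedule,
                              c(IID = 0.05, PI = 0.15, SO = 0.7, SP = 0.4))
  if (any(coupling_schedule < 0 | coupling_schedule > 1)) {
    abort("coupling strengths must lie in [0, 1]", "acinet_invalid_argument")
  }
  if (any(unlist(exponent_schedule) < 0)) {
    abort("aperiodic exponents must be >= 0", "acinet_invalid_argument")
  }
  op <- unname(onset_peak)
  if (length(op) != 3L || op[1] <= 0 || op[1] >= fs / 2 || op[2] <= 0 || op[3] < 0) {
    abort("`onset_peak` must be c(center, bandwidth, amplitude) with 0 < center < fs/2",
          "acinet_invalid_argument")
  }

  structure(list(
    fs = fs, duration_s = duration_s, seed = as.integer(seed),
    exponent_schedule = exponent_schedule,
    coupling_schedule = coupling_schedule,
    lag_s = lag_s, coupling_fn = coupling_fn,
    coupling_lowpass_hz = coupling_lowpass_hz,
    onset_peak = c(center = op[1], bandwidth = op[2], amplitude = op[3]),
    onset_time_s = onset_time_s, iid_offset_s = iid_offset_s,
    soz_channel = as.integer(soz_channel)
  ), class = "sim_config")
}

#' Generate a 1/f^chi aperiodic series by spectral shaping
#'
#' White Gaussian noise is shaped in the frequency domain: Fourier amplitudes
#' are scaled by F^(-chi/2) (DC removed), giving an expected power spectrum
#' proportional to F^(-chi). The result is centred and normalized to unit
#' variance.
#'
#' @param n_samples number of samples (>= 2).
#' @param fs sampling rate in Hz.
#' @param exponent aperiodic exponent chi >= 0 (0 = white noise).
#' @param seed integer seed; identical arguments give bit-identical output.
#' @return Numeric vector of length `n_samples`, zero mean, unit variance.
#' @export
#' @examples
#' x <- gen_aperiodic_series(1024, fs = 256, exponent = 2, seed = 1)
#' sd(x)
gen_aperiodic_series <- function(n_samples, fs, exponent, seed = 0L) {
  stopifnot_scalar_num(n_samples, "n_samples", positive = TRUE)
  stopifnot_scalar_num(fs, "fs", positive = TRUE)
  stopifnot_scalar_num(exponent, "exponent")
  if (n_samples < 2) abort("`n_samples` must be >= 2", "acinet_invalid_argument")
  if (exponent < 0) abort("`exponent` must be >= 0", "acinet_invalid_argument")
  n <- as.integer(n_samples)
  w <- with_seed(seed, stats::rnorm(n))
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n          # two-sided frequency magnitude
  scale <- c(0, f[-1]^(-exponent / 2))  # drop DC
  y <- Re(stats::fft(stats::fft(w) * scale, inverse = TRUE)) / n
  y <- y - mean(y)
  s <- stats::sd(y)
  if (s > 0) y <- y / s
  y
}

#' Generate a band-limited stochastic oscillation
#'
#' Narrowband-filtered Gaussian noise: white noise passed through a
#' zero-phase 4th-order Butterworth band-pass centred on `center` with the
#' given bandwidth, then RMS-scaled to `amplitude`.
#'
#' @param n_samples number of samples.
#' @param fs sampling rate in Hz.
#' @param center centre frequency in Hz, strictly below Nyquist.
#' @param bandwidth full bandwidth in Hz.
#' @param amplitude target RMS; 0 returns an all-zero series.
#' @param seed integer seed.
#' @return Numeric vector of length `n_samples`.
#' @export
gen_oscillation <- function(n_samples, fs, center, bandwidth, amplitude, seed = 0L) {
  stopifnot_scalar_num(n_samples, "n_samples", positive = TRUE)
  stopifnot_scalar_num(fs, "fs", positive = TRUE)
  stopifnot_scalar_num(center, "center")
  stopifnot_scalar_num(bandwidth, "bandwidth", positive = TRUE)
  if (center <= 0 || center >= fs / 2) {
    abort("`center` must lie strictly between 0 and Nyquist", "acinet_invalid_argument")
  }
  n <- as.integer(n_samples)
  if (amplitude == 0) return(numeric(n))
  lo <- max(center - bandwidth / 2, 0.01)
  hi <- min(center + bandwidth / 2, fs / 2 * 0.999)
  w <- with_seed(seed, stats::rnorm(n))
  bf <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, w)
  rms <- sqrt(mean(y^2))
  if (rms > 0) y <- y * (amplitude / rms)
  y
}

# Per-sample period labels over the whole recording; samples before the
# preictal window (including the configurable interictal gap) carry the
# interictal state.
period_state <- function(cfg) {
  n <- round(cfg$duration_s * cfg$fs)
  state <- rep("IID", n)
  if (is.na(cfg$onset_time_s)) return(state)
  onset <- round(cfg$onset_time_s * cfg$fs)
  idx <- seq_len(n) - 1L  # 0-based
  state[idx >= onset - 10 * cfg$fs & idx < onset] <- "PI"
  state[idx >= onset & idx < onset + 10 * cfg$fs] <- "SO"
  state[idx >= onset + 10 * cfg$fs] <- "SP"
  state
}

coupling_transform <- function(u, fn) {
  switch(fn,
    identity  = u,
    quadratic = u^2 - mean(u^2),
    sigmoid   = tanh(2 * u)
  )
}

#' Generate a directionally coupled two-channel recording
#'
#' Channel X (the driver) is an aperiodic 1/f^chi background plus, from
#' seizure onset onward, the configured ictal oscillation. Channel Y mixes
#' its own aperiodic noise with a delayed, optionally nonlinear transform of
#' X: `Y = sqrt(1 - c^2) * noise + c * f(X delayed)`, with the coupling
#' strength c and the exponents switching abruptly at period boundaries.
#' The sqrt(1 - c^2) weighting keeps Y's variance approximately constant
#' across periods, so h2 changes are attributable to coupling, not amplitude.
#'
#' @param cfg a [sim_config()].
#' @return A list with elements `recording` (a [recording()]) and `truth`
#'   (class `ground_truth`: `true_direction` +1 when channel 1 drives
#'   channel 2, `true_lag_s`, both schedules, and `soz_channel`).
#' @export
#' @examples
#' sim <- gen_coupled_pair(sim_config(seed = 3))
#' sim$truth$true_direction
gen_coupled_pair <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  fs <- cfg$fs
  n <- round(cfg$duration_s * fs)
  state <- period_state(cfg)
  runs <- rle(state)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)

  piecewise_aperiodic <- function(schedule, stream) {
    out <- numeric(n)
    for (i in seq_along(runs$values)) {
      seg <- starts[i]:ends[i]
      out[seg] <- gen_aperiodic_series(length(seg), fs,
                                       schedule[[runs$values[i]]],
                                       seed = derive_seed(cfg$seed, stream * 17 + i))
    }
    out
  }

  x <- piecewise_aperiodic(cfg$exponent_schedule$soz, 1L)
  onset_i <- if (is.na(cfg$onset_time_s)) n else round(cfg$onset_time_s * fs)
  ict_full <- numeric(n)
  if (cfg$onset_peak[["amplitude"]] > 0 && onset_i < n) {
    ict_full[(onset_i + 1):n] <- gen_oscillation(
      n - onset_i, fs,
      cfg$onset_peak[["center"]], cfg$onset_peak[["bandwidth"]],
      cfg$onset_peak[["amplitude"]], seed = derive_seed(cfg$seed, 101L))
    x <- x + ict_full
  }

  w <- piecewise_aperiodic(cfg$exponent_schedule$nonsoz, 2L)

  lag_n <- round(cfg$lag_s * fs)
  delay <- function(v) if (lag_n > 0) c(numeric(lag_n), v[1:(n - lag_n)]) else v
  g <- coupling_transform(delay(x), cfg$coupling_fn)
  lp <- cfg$coupling_lowpass_hz
  if (!is.na(lp) && lp < fs / 2) {
    bf <- signal::butter(1, lp / (fs / 2), type = "low")
    g <- as.numeric(signal::filtfilt(bf, g))
  }
  sg <- stats::sd(g)
  if (sg > 0) g <- (g - mean(g)) / sg
  cvec <- cfg$coupling_schedule[state]
  # the ictal rhythm also propagates to the follower directly (delayed and
  # weighted by the period's coupling strength), as early spread does
  y <- sqrt(1 - cvec^2) * w + cvec * g + cvec * delay(ict_full)

  scale_uV <- 50
  data <- rbind(x, y) * scale_uV
  if (cfg$soz_channel == 2L) data <- data[2:1, , drop = FALSE]
  rownames(data) <- NULL
  labels <- c("ch1", "ch2")
  soz_flags <- if (cfg$soz_channel == 1L) {
    c(ch1 = "SOZ", ch2 = "non-SOZ")
  } else {
    c(ch1 = "non-SOZ", ch2 = "SOZ")
  }
  rec <- recording(data, fs = fs, channel_labels = labels, soz_flags = soz_flags)
  truth <- structure(list(
    true_direction = if (cfg$soz_channel == 1L) 1L else -1L,
    true_lag_s = lag_n / fs,
    coupling_schedule = cfg$coupling_schedule,
    exponent_schedule = cfg$exponent_schedule,
    soz_channel = labels[cfg$soz_channel]
  ), class = "ground_truth")
  list(recording = rec, truth = truth)
}

#' Generate a full seizure scenario with annotation and ground truth
#'
#' Wraps [gen_coupled_pair()] with the default period schedules (coupling
#' c = 0.05/0.15/0.7/0.4 and SOZ exponent chi = 2.0/1.8/1.2/1.5 over
#' IID/PI/SO/SP) and attaches a seizure annotation at the configured onset.
#'
#' @param cfg a [sim_config()]; its schedules are used as-is, so passing the
#'   defaults yields the canonical scenario.
#' @return A list with `recording`, `annotation` (a [seizure_annotation()])
#'   and `truth`.
#' @export
gen_seizure_scenario <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.na(cfg$onset_time_s)) {
    abort("a seizure scenario needs an onset time", "acinet_invalid_argument")
  }
  if (cfg$duration_s < cfg$onset_time_s + 20 ||
      cfg$onset_time_s < cfg$iid_offset_s + 10) {
    abort("configured periods do not fit the recording", "acinet_invalid_argument")
  }
  sim <- gen_coupled_pair(cfg)
  ann <- seizure_annotation(onset_s = cfg$onset_time_s)
  list(recording = sim$recording, annotation = ann, truth = sim$truth)
}
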