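# Welch PSD estimation and parameterization of the spectrum into an
# aperiodic power-law component plus Gaussian oscillatory peaks, with the
# excitation/inhibition proxy read off the aperiodic exponent.

#' Welch power spectral density
#'
#' One-sided, density-normalized averaged periodogram with a Hann taper and
#' per-segment mean removal. The frequency resolution is `1/segment_s`.
#'
#' @param x numeric time series.
#' @param fs sampling rate in Hz.
#' @param segment_s segment length in seconds (default 2, i.e. 0.5 Hz
#'   resolution; use 0.5 for the coarse legacy setting).
#' @param overlap_frac fractional overlap between segments in \[0, 1)
#'   (default 0.5).
#' @return An object of class `power_spectrum`: list with `freqs` (Hz) and
#'   `power` ((unit^2)/Hz), plus the estimation settings.
#' @export
#' @examples
#' x <- gen_aperiodic_series(4096, 512, exponent = 1, seed = 1)
#' ps <- welch_psd(x, 512)
#' head(ps$freqs)
welch_psd <- function(x, fs, segment_s = 2, overlap_frac = 0.5) {
  stopifnot_scalar_num(fs, "fs", positive = TRUE)
  stopifnot_scalar_num(segment_s, "segment_s", positive = TRUE)
  if (overlap_frac < 0 || overlap_frac >= 1) {
    abort("`overlap_frac` must lie in [0, 1)", "acinet_invalid_argument")
  }
  nper <- round(segment_s * fs)
  if (nper < 8) abort("segment too short (< 8 samples)", "acinet_invalid_argument")
  if (nper > length(x)) {
    abort("segment longer than the signal", "acinet_invalid_argument")
  }
  hop <- max(1L, nper - floor(nper * overlap_frac))
  starts <- seq(1L, length(x) - nper + 1L, by = hop)
  k <- 0:(nper - 1)
  w <- 0.5 - 0.5 * cos(2 * pi * k / nper)   # periodic Hann
  u <- sum(w^2)
  nfreq <- floor(nper / 2) + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nper - 1)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg)[1:nfreq])^2
    acc <- acc + sp
  }
  pxx <- acc / (length(starts) * fs * u)
  # one-sided: double every bin except DC (and Nyquist when nper is even)
  dbl <- rep(2, nfreq)
  dbl[1] <- 1
  if (nper %% 2 == 0) dbl[nfreq] <- 1
  pxx <- pxx * dbl
  structure(list(
    freqs = k[1:nfreq] * fs / nper, power = pxx, fs = fs,
    segment_s = segment_s, overlap_frac = overlap_frac,
    n_segments = length(starts)
  ), class = "power_spectrum")
}

#' Fit the aperiodic (1/f-like) component of a power spectrum
#'
#' In `fixed` mode (knee k = 0) the aperiodic component is a straight line
#' in log10-log10 space, `log10 P = b - chi * log10 F`. The fit is robust to
#' oscillatory peaks: an initial least-squares line is refit on the points
#' whose residuals fall below the `robust_keep` quantile, and the exclusion
#' is iterated so that broad oscillatory bumps are eroded progressively
#' rather than only at their tips. `knee` mode fits
#' `L = b - log10(k + F^chi)` by Levenberg-Marquardt.
#'
#' @param ps a [welch_psd()] result, or a list with `freqs` and `power`.
#' @param fit_range frequency interval in Hz (default `c(1, 80)`).
#' @param mode `"fixed"` (default) or `"knee"`.
#' @param robust_keep residual quantile kept in the robust refit
#'   (default 0.975).
#' @return List with `offset` (b, log10 units), `knee` (k, 0 in fixed mode)
#'   and `exponent` (chi).
#' @export
fit_aperiodic <- function(ps, fit_range = c(1, 80), mode = c("fixed", "knee"),
                          robust_keep = 0.975) {
  mode <- match.arg(mode)
  f <- ps$freqs; p <- ps$power
  sel <- f >= fit_range[1] & f <= fit_range[2] & f > 0 & p > 0
  if (sum(sel) < 5) abort("fewer than 5 usable points in fit range", "acinet_fit_error")
  lf <- log10(f[sel]); lp <- log10(p[sel])
  fit <- stats::lm(lp ~ lf)
  if (mode == "fixed") {
    keep <- rep(TRUE, length(lf))
    if (robust_keep < 1) {
      for (it in 1:5) {
        r <- lp[keep] - stats::fitted(fit)
        thr <- stats::quantile(r, robust_keep)
        drop_now <- which(keep)[r > thr]
        if (!length(drop_now) || sum(keep) - length(drop_now) < 5) break
        keep[drop_now] <- FALSE
        fit <- stats::lm(lp[keep] ~ lf[keep])
      }
    }
    cf <- stats::coef(fit)
    list(offset = unname(cf[1]), knee = 0, exponent = unname(-cf[2]))
  } else {
    cf <- stats::coef(fit)
    start <- c(b = unname(cf[1]), k = 0, chi = unname(max(-cf[2], 0.1)))
    res_fn <- function(par) {
      lp - (par[1] - log10(pmax(par[2], 0) + (10^lf)^par[3]))
    }
    out <- minpack.lm::nls.lm(par = start, fn = res_fn,
                              lower = c(-Inf, 0, 0), upper = c(Inf, Inf, 10))
    par <- out$par
    list(offset = unname(par[1]), knee = unname(par[2]), exponent = unname(par[3]))
  }
}

gaussian_sum <- function(freqs, peaks) {
  g <- numeric(length(freqs))
  if (!nrow(peaks)) return(g)
  for (i in seq_len(nrow(peaks))) {
    g <- g + peaks$amplitude[i] *
      exp(-(freqs - peaks$center[i])^2 / (2 * peaks$width[i]^2))
  }
  g
}

#' Extract Gaussian oscillatory peaks from a flattened spectrum
#'
#' Iterative extraction on the aperiodic-removed log10 spectrum: the maximum
#' residual point seeds a Gaussian if it exceeds both the relative threshold
#' (`threshold` times the SD of the flattened spectrum) and the absolute
#' floor `min_height`; its width is guessed from the half-height extent,
#' clamped to the width limits; the Gaussian is subtracted and the search
#' repeats up to `max_n` times. All seeded Gaussians are then jointly refined
#' by bounded Levenberg-Marquardt least squares.
#'
#' @param freqs frequencies in Hz.
#' @param flat flattened spectrum: log10 power minus the aperiodic fit.
#' @param max_n maximum number of peaks (default 3).
#' @param width_limits limits in Hz on the full width `2w` of a peak
#'   (default `c(0.5, 12)`, i.e. Gaussian width `w` in \[0.25, 6\]).
#' @param threshold relative detection threshold in SD units (default 2).
#' @param min_height absolute minimum peak height in log10-power units
#'   (default 0.3); prevents fitting stochastic periodogram fluctuations,
#'   whose maxima scale with the residual SD and therefore always exceed a
#'   purely relative threshold somewhere on a dense frequency grid.
#' @return data.frame with columns `amplitude` (log10 units), `center` (Hz)
#'   and `width` (Hz, Gaussian SD-like); zero rows when nothing qualifies.
#' @export
fit_peaks <- function(freqs, flat, max_n = 3, width_limits = c(0.5, 12),
                      threshold = 2, min_height = 0.3) {
  w_lo <- width_limits[1] / 2
  w_hi <- width_limits[2] / 2
  resid <- flat
  guesses <- list()
  for (it in seq_len(max_n)) {
    sdr <- stats::sd(resid)
    i <- which.max(resid)
    h <- resid[i]
    if (!is.finite(h) || h < threshold * sdr || h < min_height) break
    cf <- freqs[i]
    half <- h / 2
    li <- i; while (li > 1 && resid[li - 1] > half) li <- li - 1
    ri <- i; while (ri < length(resid) && resid[ri + 1] > half) ri <- ri + 1
    fwhm <- max(freqs[ri] - freqs[li], diff(freqs[1:2]))
    wg <- min(max(fwhm / 2.355, w_lo), w_hi)
    guesses[[length(guesses) + 1L]] <- c(a = h, c = cf, w = wg)
    resid <- resid - h * exp(-(freqs - cf)^2 / (2 * wg^2))
  }
  empty <- data.frame(amplitude = numeric(0), center = numeric(0),
                      width = numeric(0))
  if (!length(guesses)) return(empty)
  par0 <- unlist(guesses)
  np <- length(guesses)
  lower <- rep(c(0, min(freqs), w_lo), np)
  upper <- rep(c(Inf, max(freqs), w_hi), np)
  res_fn <- function(par) {
    pk <- matrix(par, ncol = 3, byrow = TRUE)
    flat - gaussian_sum(freqs, data.frame(amplitude = pk[, 1],
                                          center = pk[, 2], width = pk[, 3]))
  }
  out <- minpack.lm::nls.lm(par = par0, fn = res_fn, lower = lower,
                            upper = upper,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  pk <- matrix(out$par, ncol = 3, byrow = TRUE)
  peaks <- data.frame(amplitude = pk[, 1], center = pk[, 2], width = pk[, 3])
  peaks <- peaks[peaks$amplitude > 0, , drop = FALSE]
  peaks <- peaks[order(-peaks$amplitude), , drop = FALSE]
  rownames(peaks) <- NULL
  peaks
}

#' Parameterize a power spectrum into aperiodic and periodic components
#'
#' Full decomposition loop: robust aperiodic fit, flatten, iterative Gaussian
#' peak extraction, subtraction of the peak model, aperiodic refit on the
#' peak-removed spectrum, and goodness of fit of the combined model against
#' the log10 spectrum.
#'
#' @param ps a [welch_psd()] result.
#' @param fit_range frequency range in Hz (default `c(1, 80)`).
#' @param max_n_peaks maximum number of Gaussian peaks (default 3).
#' @param width_limits Hz limits on peak full width (default `c(0.5, 12)`).
#' @param threshold relative peak threshold in SD units (default 2).
#' @param min_height absolute peak floor in log10 units (default 0.3).
#' @param mode aperiodic mode, `"fixed"` (knee = 0, default) or `"knee"`.
#' @return An object of class `spectrum_model` with fields `offset`, `knee`,
#'   `exponent`, `peaks`, `fit_range`, `mode` and `gof` (r_squared, mae).
#' @export
#' @examples
#' x <- gen_aperiodic_series(512 * 30, 512, exponent = 2, seed = 7)
#' m <- parameterize_spectrum(welch_psd(x, 512))
#' m$exponent
parameterize_spectrum <- function(ps, fit_range = c(1, 80), max_n_peaks = 3,
                                  width_limits = c(0.5, 12), threshold = 2,
                                  min_height = 0.3, mode = "fixed") {
  f <- ps$freqs; p <- ps$power
  sel <- f >= fit_range[1] & f <= fit_range[2] & f > 0 & p > 0
  if (sum(sel) < 5) abort("fewer than 5 usable points in fit range", "acinet_fit_error")
  fr <- f[sel]; lp <- log10(p[sel])
  sub <- list(freqs = fr, power = 10^lp)
  ap1 <- fit_aperiodic(sub, fit_range = fit_range, mode = mode)
  l1 <- aperiodic_log10(ap1, fr)
  peaks <- fit_peaks(fr, lp - l1, max_n = max_n_peaks,
                     width_limits = width_limits, threshold = threshold,
                     min_height = min_height)
  lp_noperiodic <- lp - gaussian_sum(fr, peaks)
  ap2 <- fit_aperiodic(list(freqs = fr, power = 10^lp_noperiodic),
                       fit_range = fit_range, mode = mode, robust_keep = 1)
  model_lp <- aperiodic_log10(ap2, fr) + gaussian_sum(fr, peaks)
  resid <- lp - model_lp
  gof <- list(r_squared = 1 - sum(resid^2) / sum((lp - mean(lp))^2),
              mae = mean(abs(resid)))
  structure(list(
    offset = ap2$offset, knee = ap2$knee, exponent = ap2$exponent,
    peaks = peaks, fit_range = fit_range, mode = mode, gof = gof
  ), class = "spectrum_model")
}

aperiodic_log10 <- function(ap, freqs) {
  if (ap$knee == 0) {
    ap$offset - ap$exponent * log10(freqs)
  } else {
    ap$offset - log10(ap$knee + freqs^ap$exponent)
  }
}

#' @export
print.spectrum_model <- function(x, ...) {
  cat(sprintf("<spectrum_model> offset=%.3f knee=%.3g exponent=%.3f (%s mode)\n",
              x$offset, x$knee, x$exponent, x$mode))
  cat(sprintf("  fit range %g-%g Hz, R^2=%.4f, MAE=%.4f, %d peak(s)\n",
              x$fit_range[1], x$fit_range[2], x$gof$r_squared, x$gof$mae,
              nrow(x$peaks)))
  if (nrow(x$peaks)) print(x$peaks)
  invisible(x)
}

#' Evaluate a spectrum model on a frequency grid
#'
#' Forward model: `10^(L(F) + sum of Gaussians)`.
#'
#' @param m a `spectrum_model`.
#' @param freqs frequencies in Hz; a warning is issued outside the fit range.
#' @return A `power_spectrum` on the requested grid.
#' @export
model_spectrum <- function(m, freqs) {
  stopifnot(inherits(m, "spectrum_model"))
  if (any(freqs < m$fit_range[1] | freqs > m$fit_range[2])) {
    warning("evaluating spectrum model outside its fit range")
  }
  lp <- aperiodic_log10(m, freqs) + gaussian_sum(freqs, m$peaks)
  structure(list(freqs = freqs, power = 10^lp), class = "power_spectrum")
}

#' Excitation/inhibition proxy from the aperiodic exponent
#'
#' The E:I index is minus the fitted aperiodic exponent: a flatter spectrum
#' (smaller chi) gives a larger value, read ordinally as a higher
#' excitation-to-inhibition balance. Only the ordering carries meaning, not
#' the absolute scale.
#'
#' @param m a `spectrum_model` fitted in fixed mode.
#' @return Numeric E:I index (`-exponent`).
#' @export
ei_index <- function(m) {
  stopifnot(inherits(m, "spectrum_model"))
  -m$exponent
}
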