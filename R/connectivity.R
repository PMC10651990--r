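# Frequency-specific nonlinear functional coupling: band filtering, the
# nonparametric-regression correlation h2 with lag scanning, sliding
# windows, and the direction index built from h2 and lag asymmetry.

#' The seven EEG analysis bands
#'
#' Fixed half-open partition of 0.5-80 Hz: delta \[0.5,4), theta \[4,8),
#' alpha \[8,13), low beta \[13,20), high beta \[20,30), low gamma \[30,45),
#' high gamma \[45,80\] (closed at 80).
#'
#' @return data.frame with columns `name`, `lo`, `hi`.
#' @export
band_table <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta1", "beta2", "gamma1", "gamma2"),
    lo = c(0.5, 4, 8, 13, 20, 30, 45),
    hi = c(4, 8, 13, 20, 30, 45, 80),
    stringsAsFactors = FALSE
  )
}

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward 4th-order Butterworth, so the output has no net group
#' delay (phase distortion would corrupt the lag estimates downstream).
#'
#' @param x numeric time series.
#' @param fs sampling rate in Hz.
#' @param band either a band name from [band_table()], or `c(lo, hi)` in Hz.
#' @return Filtered series of the same length.
#' @export
bandpass <- function(x, fs, band) {
  if (is.character(band)) {
    bt <- band_table()
    i <- match(band, bt$name)
    if (is.na(i)) abort(sprintf("unknown band '%s'", band), "acinet_invalid_argument")
    band <- c(bt$lo[i], bt$hi[i])
  }
  if (band[2] >= fs / 2) {
    abort("band upper edge must be below Nyquist", "acinet_invalid_argument")
  }
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Nonlinear correlation coefficient h2 (fixed alignment)
#'
#' Fraction of Y's variance explained by a nonparametric piecewise-linear
#' regression of Y on X: samples are sorted into `nbins` equal-count bins of
#' X; the curve passes through (per-bin median of X, per-bin mean of Y) and
#' is extended linearly beyond the outer bins. h2 = 1 - residual
#' variance / total variance, clipped to \[0, 1\]. Asymmetric in its
#' arguments: a non-invertible X->Y map yields h2(X->Y) >> h2(Y->X).
#'
#' @param x,y numeric vectors of equal length (at least `10 * nbins`).
#' @param nbins number of regression bins; default
#'   `max(4, floor(sqrt(n) / 2))`.
#' @return h2 in \[0, 1\]. A constant `x` returns 0; a constant `y` is an
#'   error (undefined variance ratio).
#' @export
#' @examples
#' x <- runif(2000, -1, 1)
#' nonlinear_regression_h2(x, x^2 + rnorm(2000, sd = 0.05))
nonlinear_regression_h2 <- function(x, y, nbins = NULL) {
  n <- length(x)
  if (length(y) != n) abort("x and y must have equal length", "acinet_invalid_argument")
  if (is.null(nbins)) nbins <- max(4L, floor(sqrt(n) / 2))
  nbins <- as.integer(nbins)
  if (n < 10L * nbins) {
    abort("need at least 10 samples per bin", "acinet_invalid_argument")
  }
  vy <- mean((y - mean(y))^2)
  if (vy == 0) abort("VAR(y) is zero; h2 undefined", "acinet_undefined_variance")
  if (stats::sd(x) == 0) return(0)

  o <- order(x)
  xs <- x[o]; ys <- y[o]
  edges <- floor(seq(0, n, length.out = nbins + 1L))
  lo <- edges[-length(edges)] + 1L
  hi <- edges[-1]
  # per-bin median of sorted x = middle element(s); per-bin mean of y by cumsum
  mi <- (lo + hi) / 2
  xm <- (xs[floor(mi)] + xs[ceiling(mi)]) / 2
  cs <- cumsum(ys)
  ym <- (cs[hi] - c(0, cs[hi])[seq_along(hi)]) / (hi - lo + 1L)

  # collapse duplicated abscissae (heavy ties in x)
  if (any(diff(xm) <= 0)) {
    grp <- cumsum(c(TRUE, diff(xm) > 0))
    xm <- tapply(xm, grp, mean)
    ym <- tapply(ym, grp, mean)
    names(xm) <- names(ym) <- NULL
  }
  if (length(xm) < 2L) return(0)

  # piecewise-linear interpolation with linear extension of the end segments
  j <- findInterval(x, xm, all.inside = TRUE)
  slope <- (ym[j + 1L] - ym[j]) / (xm[j + 1L] - xm[j])
  yhat <- ym[j] + slope * (x - xm[j])
  res <- mean((y - yhat)^2)
  min(max(1 - res / vy, 0), 1)
}

#' Scan h2 over integer-sample lags
#'
#' Evaluates the nonlinear correlation at every shift tau in
#' \[-max_lag, +max_lag\] samples, where positive tau means Y follows X
#' (Y is regressed on X delayed by tau). Windows are trimmed to the
#' overlapping support, never zero-padded. Ties are broken toward the
#' smallest |tau|, then toward negative tau; lags whose h2 falls within
#' `lag_tol` of the maximum count as tied, since h2 differences below the
#' estimator's own finite-sample noise (about nbins/n, the overfitting
#' scale of the piecewise regression) carry no evidence about the lag.
#' Without this, an uninformative near-flat profile hands the lag to
#' whichever scan-boundary fluctuation is largest.
#'
#' @param x,y numeric vectors of equal length.
#' @param fs sampling rate in Hz.
#' @param max_lag_s maximum lag in seconds (default 0.1).
#' @param nbins regression bins, passed to [nonlinear_regression_h2()];
#'   default derived from the full window length.
#' @param lag_tol h2 near-tie tolerance for the lag argmax (default 0.02).
#' @return List with `h2` (maximum over lags), `tau` (its lag in seconds),
#'   and `profile` (data.frame of all lags).
#' @export
h2_lag_scan <- function(x, y, fs, max_lag_s = 0.1, nbins = NULL,
                        lag_tol = 0.02) {
  n <- length(x)
  if (length(y) != n) abort("x and y must have equal length", "acinet_invalid_argument")
  L <- floor(max_lag_s * fs)
  if (L < 1) abort("max_lag_s must cover at least one sample", "acinet_invalid_argument")
  if (is.null(nbins)) nbins <- max(4L, floor(sqrt(n) / 2))
  if (n - L < 10L * nbins) {
    abort("window too short for this lag range", "acinet_invalid_argument")
  }
  taus <- -L:L
  h2s <- numeric(length(taus))
  for (i in seq_along(taus)) {
    tau <- taus[i]
    if (tau >= 0) {
      xs <- x[1:(n - tau)]; yshift <- y[(1 + tau):n]
    } else {
      xs <- x[(1 - tau):n]; yshift <- y[1:(n + tau)]
    }
    h2s[i] <- nonlinear_regression_h2(xs, yshift, nbins = nbins)
  }
  # near-ties resolved toward smallest |tau|, then negative tau
  cand <- which(h2s >= max(h2s) - lag_tol)
  best <- cand[order(abs(taus[cand]), taus[cand])][1]
  list(h2 = max(h2s), tau = taus[best] / fs,
       profile = data.frame(tau_s = taus / fs, h2 = h2s))
}

#' Direction index from h2 and lag asymmetry
#'
#' `D = (sgn(delta_h2) + sgn(delta_t)) / 2` with `sgn(0) = 0`, so D takes
#' values in \{-1, -0.5, 0, 0.5, 1\}. D = +1 indicates that Y is influenced
#' by X (X leads); D = -1 the reverse. Swapping the roles of the two signals
#' flips both differences, so D is antisymmetric.
#'
#' @param delta_h2 `h2(X->Y) - h2(Y->X)`.
#' @param delta_t `tau(X->Y) - tau(Y->X)` in seconds.
#' @return D in \{-1, -0.5, 0, 0.5, 1\}; vectorized.
#' @export
direction_index <- function(delta_h2, delta_t) {
  if (any(!is.finite(delta_h2)) || any(!is.finite(delta_t))) {
    abort("delta_h2 and delta_t must be finite", "acinet_invalid_argument")
  }
  (sign(delta_h2) + sign(delta_t)) / 2
}

#' Sliding-window bidirectional h2 analysis
#'
#' For each window: lag scans in both directions, their asymmetries
#' `delta_h2 = h2(X->Y) - h2(Y->X)` and `delta_t = tau(X->Y) - tau(Y->X)`,
#' and the window's direction index. A 10-s segment at the default 2-s
#' window and 1-s step yields 9 windows.
#'
#' @param x,y numeric vectors of equal length.
#' @param fs sampling rate in Hz.
#' @param window_s window length in seconds (default 2).
#' @param step_s step between windows in seconds (default 1).
#' @param max_lag_s maximum scanned lag in seconds (default 0.1).
#' @param nbins regression bins (default from window length).
#' @param lag_tol h2 near-tie tolerance for the lag argmax (see
#'   [h2_lag_scan()]).
#' @param asym_tol dead-zone on the estimated h2 asymmetry (default 0.05):
#'   |delta_h2| below it is treated as no asymmetry (sgn = 0) when forming
#'   the window's direction index, because h2 estimates on short
#'   autocorrelated windows fluctuate on this scale between replications,
#'   so smaller differences carry no directional evidence. The reported
#'   `delta_h2` column keeps the raw difference.
#' @return data.frame of class `h2_windows` with one row per window:
#'   `t_start`, `h2_xy`, `h2_yx`, `tau_xy`, `tau_yx`, `delta_h2`,
#'   `delta_t`, `D`.
#' @export
sliding_h2 <- function(x, y, fs, window_s = 2, step_s = 1, max_lag_s = 0.1,
                       nbins = NULL, lag_tol = 0.02, asym_tol = 0.05) {
  n <- length(x)
  wn <- round(window_s * fs)
  sn <- max(1L, round(step_s * fs))
  if (wn > n) abort("signal shorter than one window", "acinet_invalid_argument")
  starts <- seq(1L, n - wn + 1L, by = sn)
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    s <- starts[k]
    xi <- x[s:(s + wn - 1L)]
    yi <- y[s:(s + wn - 1L)]
    fwd <- h2_lag_scan(xi, yi, fs, max_lag_s, nbins, lag_tol)
    rev <- h2_lag_scan(yi, xi, fs, max_lag_s, nbins, lag_tol)
    dh2 <- fwd$h2 - rev$h2
    dt <- fwd$tau - rev$tau
    dh2_eff <- if (abs(dh2) < asym_tol) 0 else dh2
    out[[k]] <- data.frame(
      t_start = (s - 1L) / fs,
      h2_xy = fwd$h2, h2_yx = rev$h2,
      tau_xy = fwd$tau, tau_yx = rev$tau,
      delta_h2 = dh2, delta_t = dt,
      D = direction_index(dh2_eff, dt)
    )
  }
  res <- do.call(rbind, out)
  class(res) <- c("h2_windows", "data.frame")
  res
}

#' Per-period band-limited connectivity between two channels
#'
#' Band-pass filters the two analysis channels over the whole recording,
#' then runs the sliding h2 analysis within each analysis period and
#' aggregates: `mean_h2` is the mean over windows of
#' `(h2_xy + h2_yx) / 2` (the two-step average), `mean_D` the mean of
#' per-window direction indices.
#'
#' @param rec a [recording()].
#' @param seg a [segment_periods()] result covering IID/PI/SO/SP.
#' @param band band name or `c(lo, hi)` Hz, passed to [bandpass()].
#' @param channels indices or labels of the two analysis channels
#'   (default the first two).
#' @param ... further arguments to [sliding_h2()].
#' @return data.frame with one row per period (`period`, `mean_h2`,
#'   `mean_D`, `n_windows`); the per-window tables are attached as
#'   `attr(, "windows")`.
#' @export
period_connectivity <- function(rec, seg, band, channels = c(1, 2), ...) {
  stopifnot(inherits(rec, "recording"), inherits(seg, "period_segments"))
  if (is.character(channels)) channels <- match(channels, rec$channel_labels)
  if (length(channels) != 2 || anyNA(channels)) {
    abort("exactly two valid analysis channels are required", "acinet_invalid_argument")
  }
  need <- c("IID", "PI", "SO", "SP")
  if (!all(need %in% seg$period)) {
    abort("all four analysis periods must be present", "acinet_invalid_argument")
  }
  fx <- bandpass(rec$data[channels[1], ], rec$fs, band)
  fy <- bandpass(rec$data[channels[2], ], rec$fs, band)
  windows <- list()
  rows <- vector("list", length(need))
  for (i in seq_along(need)) {
    p <- need[i]
    r <- seg[seg$period == p, ]
    idx <- (r$start + 1L):r$end     # half-open [start, end) in 0-based samples
    w <- sliding_h2(fx[idx], fy[idx], rec$fs, ...)
    windows[[p]] <- w
    rows[[i]] <- data.frame(
      period = p,
      mean_h2 = mean((w$h2_xy + w$h2_yx) / 2),
      mean_D = mean(w$D),
      n_windows = nrow(w)
    )
  }
  res <- do.call(rbind, rows)
  attr(res, "windows") <- windows
  res
}
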