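# Orchestration: period segmentation, onset-band selection, per-period
# connectivity and excitability, paired statistics with FDR correction, and
# the seizure-onset-zone call.

#' Segment a recording into the four analysis periods
#'
#' Half-open sample intervals (0-based) of 10 s each around seizure onset:
#' preictal ends at onset, onset starts at it, propagation covers the next
#' 10-20 s, and the interictal window ends `iid_offset_s` before onset.
#' Errors rather than truncates when a period does not fit.
#'
#' @param ann a [seizure_annotation()].
#' @param fs sampling rate in Hz.
#' @param iid_offset_s gap in seconds between the interictal window's end
#'   and onset (default 60; 7200 matches a 2-hour clinical separation).
#' @param n_samples optional recording length for the upper bound check.
#' @return data.frame of class `period_segments` with columns `period`,
#'   `start`, `end` (samples, half-open).
#' @export
#' @examples
#' segment_periods(seizure_annotation(100), fs = 512)
segment_periods <- function(ann, fs, iid_offset_s = 60, n_samples = NULL) {
  stopifnot(inherits(ann, "seizure_annotation"))
  stopifnot_scalar_num(fs, "fs", positive = TRUE)
  onset <- round(ann$onset_s * fs)
  len <- round(10 * fs)
  off <- round(iid_offset_s * fs)
  seg <- data.frame(
    period = c("IID", "PI", "SO", "SP"),
    start = c(onset - off - len, onset - len, onset, onset + len),
    end = c(onset - off, onset, onset + len, onset + 2L * len)
  )
  if (any(seg$start < 0)) {
    abort("recording too short before onset for the requested periods",
          "acinet_invalid_argument")
  }
  if (!is.null(n_samples) && any(seg$end > n_samples)) {
    abort("recording too short after onset for the requested periods",
          "acinet_invalid_argument")
  }
  class(seg) <- c("period_segments", "data.frame")
  seg
}

#' Assign a center frequency to its EEG band
#'
#' The seven bands form a half-open partition of \[0.5, 80\] Hz (the top
#' band is closed at 80), so every admissible center maps to exactly one
#' band.
#'
#' @param center frequency in Hz, within \[0.5, 80\].
#' @return One row of [band_table()].
#' @export
#' @examples
#' assign_band(10)$name
assign_band <- function(center) {
  stopifnot_scalar_num(center, "center")
  if (center < 0.5 || center > 80) {
    abort("center frequency outside [0.5, 80] Hz", "acinet_invalid_argument")
  }
  bt <- band_table()
  i <- which(center >= bt$lo & (center < bt$hi | (center == 80 & bt$hi == 80)))
  bt[i[1], ]
}

#' Select the patient-specific onset band
#'
#' Parameterizes the seizure-onset spectrum of the designated channel(s)
#' and assigns the largest-amplitude peak's center frequency to its band.
#' With no detectable peak, falls back (with a warning) to the band holding
#' the maximum of the flattened spectrum.
#'
#' @param rec a [recording()].
#' @param seg a [segment_periods()] result.
#' @param channel index/label of the channel to parameterize; `NULL`
#'   (default) examines both analysis channels and takes the larger peak.
#' @param ... arguments passed to [parameterize_spectrum()].
#' @return One row of [band_table()], with the chosen center frequency
#'   attached as `attr(, "center")`.
#' @export
select_onset_band <- function(rec, seg, channel = NULL, ...) {
  stopifnot(inherits(rec, "recording"), inherits(seg, "period_segments"))
  r <- seg[seg$period == "SO", ]
  if (!nrow(r)) abort("no seizure-onset segment", "acinet_invalid_argument")
  idx <- (r$start + 1L):r$end
  chans <- if (is.null(channel)) seq_len(min(2L, nrow(rec$data))) else channel
  if (is.character(chans)) chans <- match(chans, rec$channel_labels)
  best <- NULL
  flat_best <- NULL
  for (ch in chans) {
    ps <- welch_psd(rec$data[ch, idx], rec$fs)
    m <- parameterize_spectrum(ps, ...)
    if (nrow(m$peaks)) {
      cand <- m$peaks[1, ]
      if (is.null(best) || cand$amplitude > best$amplitude) best <- cand
    }
    # keep a flattened spectrum for the fallback path
    sel <- ps$freqs >= m$fit_range[1] & ps$freqs <= m$fit_range[2] & ps$power > 0
    flat <- log10(ps$power[sel]) - aperiodic_log10(m, ps$freqs[sel])
    fmax <- ps$freqs[sel][which.max(flat)]
    if (is.null(flat_best)) flat_best <- fmax
  }
  if (is.null(best)) {
    warning("no oscillatory peak detected at onset; falling back to the ",
            "flattened-spectrum maximum")
    center <- flat_best
  } else {
    center <- best$center
  }
  center <- min(max(center, 0.5), 80)
  band <- assign_band(center)
  attr(band, "center") <- center
  band
}

#' Normality-gated paired comparison
#'
#' Shapiro-Wilk tests at `alpha_normality` on both samples and on their
#' differences decide between a paired t test (all normal) and a Wilcoxon
#' matched-pairs signed-rank test; two-sided either way. All-zero
#' differences are degenerate: reported as no effect (p = 1) with a warning.
#'
#' @param a,b paired numeric samples of equal length (>= 3).
#' @param alpha_normality significance level of the normality gate
#'   (default 0.05).
#' @param comparison optional label carried into the result.
#' @return data.frame with `comparison`, `test`, `statistic`, `p_raw`,
#'   `n_pairs`.
#' @export
paired_compare <- function(a, b, alpha_normality = 0.05, comparison = NA_character_) {
  if (length(a) != length(b) || length(a) < 3) {
    abort("paired samples must have equal length >= 3", "acinet_invalid_argument")
  }
  d <- a - b
  if (all(d == 0)) {
    warning("all paired differences are zero; reporting no effect")
    return(data.frame(comparison = comparison, test = "degenerate",
                      statistic = 0, p_raw = 1, n_pairs = length(a)))
  }
  shapiro_p <- function(x) {
    if (stats::sd(x) == 0) return(0)  # constant sample: treat as non-normal
    tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0)
  }
  normal <- min(shapiro_p(a), shapiro_p(b), shapiro_p(d)) > alpha_normality
  if (normal) {
    ht <- stats::t.test(a, b, paired = TRUE)
    test <- "paired-t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
    test <- "wilcoxon-signed-rank"
  }
  data.frame(comparison = comparison, test = test,
             statistic = unname(ht$statistic), p_raw = ht$p.value,
             n_pairs = length(a))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03, 0.04))
fdr_adjust <- function(p_values) {
  if (!is.numeric(p_values) || any(!is.finite(p_values)) ||
      any(p_values < 0 | p_values > 1)) {
    abort("p-values must be finite and in [0, 1]", "acinet_invalid_argument")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Call the seizure-onset zone from connectivity and excitability
#'
#' Primary evidence is the sign of the mean direction index during seizure
#' onset: a positive mean D means channel 1 drives channel 2 and is called
#' the SOZ. Secondary evidence is which channel shows the larger
#' interictal-to-onset E:I increase. When D is exactly 0 the call is
#' indeterminate and the E:I evidence decides (flagged); when the two
#' disagree, D wins and the disagreement is flagged.
#'
#' @param conn per-period connectivity table from [period_connectivity()].
#' @param ei_table data.frame with columns `period`, `channel`, `ei`
#'   covering both channels at IID and SO.
#' @param channels labels of the two analysis channels, in the X/Y order
#'   used for the connectivity analysis.
#' @return List with `called_soz`, `mean_D_so`, `ei_evidence`, `flags`.
#' @export
classify_soz <- function(conn, ei_table, channels = c("ch1", "ch2")) {
  d_so <- conn$mean_D[conn$period == "SO"]
  if (!length(d_so)) abort("no seizure-onset connectivity row", "acinet_invalid_argument")
  ei_rise <- vapply(channels, function(ch) {
    so <- ei_table$ei[ei_table$period == "SO" & ei_table$channel == ch]
    iid <- ei_table$ei[ei_table$period == "IID" & ei_table$channel == ch]
    if (!length(so) || !length(iid)) NA_real_ else so - iid
  }, 0)
  ei_pick <- if (all(is.finite(ei_rise))) channels[which.max(ei_rise)] else NA_character_
  flags <- character(0)
  if (d_so > 0) {
    called <- channels[1]
  } else if (d_so < 0) {
    called <- channels[2]
  } else {
    called <- ei_pick
    flags <- c(flags, "indeterminate-D")
  }
  if (!is.na(ei_pick) && !identical(called, ei_pick) && d_so != 0) {
    flags <- c(flags, "ei-disagrees")
  }
  list(called_soz = called, mean_D_so = d_so, ei_evidence = ei_rise,
       flags = flags)
}

# Window-level E:I samples: slide 2-s windows (step 1 s) over a period and
# fit each window's spectrum with 1-s Welch segments (1 Hz resolution).
ei_windows <- function(x, fs, fit_range = c(1, 80)) {
  wn <- round(2 * fs); sn <- round(1 * fs)
  starts <- seq(1L, length(x) - wn + 1L, by = sn)
  vapply(starts, function(s) {
    ps <- welch_psd(x[s:(s + wn - 1L)], fs, segment_s = 1)
    m <- parameterize_spectrum(ps, fit_range = fit_range)
    ei_index(m)
  }, 0)
}

#' Run the end-to-end seizure-dynamics analysis
#'
#' Executes the full pipeline on a recording + annotation (or on a
#' simulation config): period segmentation, onset-band selection,
#' band-limited per-period connectivity, per-period spectrum models and E:I
#' indices for both channels, the four pairwise period comparisons
#' (IID-PI, IID-SO, PI-SO, SO-SP) for h2, D and E:I with FDR correction
#' within each measure family, and the SOZ call.
#'
#' Paired samples for the statistics are window-level values: the 9 sliding
#' windows of each 10-s period, paired by window index; E:I comparisons use
#' the hypothesized SOZ channel.
#'
#' @param config list with either `sim` (a [sim_config()]) or `recording` +
#'   `annotation`; optional entries: `channels` (two indices/labels,
#'   default first two), `soz_hypothesis` (channel label used for the E:I
#'   comparison family, default the first channel), `band` (`"auto"` for
#'   onset-band selection, or a band name), `iid_offset_s`, `out_dir`.
#' @return Object of class `acin_report`: `periods` (period-level mean_h2,
#'   mean_D and per-channel E:I), `stats` (12 FDR-adjusted comparisons),
#'   `soz_call`, `band`, `settings`, plus window-level detail in
#'   `windows`/`ei_windows`. Written to `out_dir` via [write_report()] when
#'   given.
#' @export
#' @examples
#' \donttest{
#' rep <- run_pipeline(list(sim = sim_config(seed = 0)))
#' rep$periods
#' }
run_pipeline <- function(config) {
  if (!is.null(config$sim)) {
    scen <- gen_seizure_scenario(config$sim)
    rec <- scen$recording
    ann <- scen$annotation
    iid_offset_s <- config$iid_offset_s %||% config$sim$iid_offset_s
    seed <- config$sim$seed
  } else {
    rec <- config$recording
    ann <- config$annotation
    if (is.null(rec) || is.null(ann)) {
      abort("config needs either `sim` or `recording` + `annotation`",
            "acinet_invalid_argument")
    }
    iid_offset_s <- config$iid_offset_s %||% 60
    seed <- config$seed %||% NA_integer_
  }
  channels <- config$channels %||% c(1L, 2L)
  if (is.character(channels)) channels <- match(channels, rec$channel_labels)
  ch_labels <- rec$channel_labels[channels]
  soz_hyp <- config$soz_hypothesis %||% ch_labels[1]

  seg <- segment_periods(ann, rec$fs, iid_offset_s = iid_offset_s,
                         n_samples = ncol(rec$data))

  band_cfg <- config$band %||% "auto"
  band <- if (identical(band_cfg, "auto")) {
    select_onset_band(rec, seg, channel = NULL)
  } else {
    bt <- band_table()
    bt[match(band_cfg, bt$name), ]
  }
  if (is.na(band$name)) abort("unknown band", "acinet_invalid_argument")

  conn <- period_connectivity(rec, seg, band = c(band$lo, band$hi),
                              channels = channels)
  windows <- attr(conn, "windows")

  periods <- c("IID", "PI", "SO", "SP")
  ei_rows <- list(); ei_win <- list()
  spectra <- list()
  for (p in periods) {
    r <- seg[seg$period == p, ]
    idx <- (r$start + 1L):r$end
    for (k in 1:2) {
      ch <- ch_labels[k]
      xseg <- rec$data[channels[k], idx]
      m <- parameterize_spectrum(welch_psd(xseg, rec$fs))
      spectra[[paste(p, ch, sep = ".")]] <- m
      ei_rows[[paste(p, ch, sep = ".")]] <-
        data.frame(period = p, channel = ch, ei = ei_index(m),
                   exponent = m$exponent, offset = m$offset)
      ei_win[[paste(p, ch, sep = ".")]] <- ei_windows(xseg, rec$fs)
    }
  }
  ei_table <- do.call(rbind, ei_rows)
  rownames(ei_table) <- NULL

  contrasts <- list(c("IID", "PI"), c("IID", "SO"), c("PI", "SO"), c("SO", "SP"))
  fam <- function(vals, measure) {
    rows <- lapply(contrasts, function(ct) {
      paired_compare(vals[[ct[1]]], vals[[ct[2]]],
                     comparison = sprintf("%s: %s vs %s", measure, ct[1], ct[2]))
    })
    out <- do.call(rbind, rows)
    out$p_fdr <- fdr_adjust(out$p_raw)
    out
  }
  h2_vals <- lapply(windows, function(w) (w$h2_xy + w$h2_yx) / 2)
  d_vals <- lapply(windows, function(w) w$D)
  ei_vals <- ei_win[paste(periods, soz_hyp, sep = ".")]
  names(ei_vals) <- periods
  stats_tbl <- rbind(fam(h2_vals, "h2"), fam(d_vals, "D"), fam(ei_vals, "EI"))
  rownames(stats_tbl) <- NULL

  soz <- classify_soz(conn, ei_table, channels = ch_labels)

  period_tbl <- conn
  attr(period_tbl, "windows") <- NULL
  for (k in 1:2) {
    period_tbl[[paste0("ei_", ch_labels[k])]] <-
      ei_table$ei[match(paste(period_tbl$period, ch_labels[k]),
                        paste(ei_table$period, ei_table$channel))]
  }

  report <- structure(list(
    periods = period_tbl,
    ei_table = ei_table,
    stats = stats_tbl,
    soz_call = soz,
    band = list(name = band$name, lo = band$lo, hi = band$hi,
                center = attr(band, "center")),
    windows = windows,
    ei_windows = ei_win,
    spectra = spectra,
    settings = list(seed = seed, iid_offset_s = iid_offset_s,
                    channels = ch_labels, soz_hypothesis = soz_hyp,
                    band_mode = band_cfg)
  ), class = "acin_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.acin_report <- function(x, ...) {
  cat("<acin_report>\n")
  cat(sprintf("  band: %s (%g-%g Hz)\n", x$band$name, x$band$lo, x$band$hi))
  print(x$periods)
  cat(sprintf("  SOZ call: %s (mean D at onset = %.3f)\n",
              x$soz_call$called_soz, x$soz_call$mean_D_so))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
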