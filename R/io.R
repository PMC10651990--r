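# Signal container, bipolar montage, and report output.

#' Construct a multichannel recording
#'
#' The signal container used by all stages: a channels-by-samples numeric
#' matrix with a sampling rate and channel metadata. Sampling rates other
#' than the clinical 256/512 Hz are allowed with a warning.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_labels unique channel labels; default `ch1..chK`.
#' @param region_labels optional named character map channel -> region
#'   (e.g. "ACC", "AIC").
#' @param soz_flags optional named character map channel -> "SOZ"/"non-SOZ".
#' @return An object of class `recording`.
#' @export
recording <- function(data, fs, channel_labels = NULL,
                      region_labels = NULL, soz_flags = NULL) {
  if (is.vector(data)) data <- matrix(data, nrow = 1L)
  if (!is.matrix(data) || !is.numeric(data)) {
    abort("`data` must be a numeric channels x samples matrix", "acinet_invalid_argument")
  }
  stopifnot_scalar_num(fs, "fs", positive = TRUE)
  if (!fs %in% c(256, 512)) {
    warning("sampling rate ", fs, " Hz is outside the usual 256/512 Hz")
  }
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(nrow(data)))
  if (length(channel_labels) != nrow(data) || anyDuplicated(channel_labels)) {
    abort("channel labels must be unique and match the number of rows",
          "acinet_invalid_argument")
  }
  structure(list(
    data = data, fs = fs, channel_labels = as.character(channel_labels),
    region_labels = region_labels, soz_flags = soz_flags
  ), class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Seizure-onset annotation
#'
#' @param onset_s onset time in seconds from recording start.
#' @param onset_pattern optional electrographic pattern tag (e.g. "LVFA").
#' @return An object of class `seizure_annotation`.
#' @export
seizure_annotation <- function(onset_s, onset_pattern = NULL) {
  stopifnot_scalar_num(onset_s, "onset_s")
  if (onset_s < 0) abort("`onset_s` must be >= 0", "acinet_invalid_argument")
  structure(list(onset_s = onset_s, onset_pattern = onset_pattern),
            class = "seizure_annotation")
}

#' Derive a bipolar montage
#'
#' Subtracts adjacent electrode contacts: each derived channel is
#' `contactA - contactB`, labelled `"A-B"`. When `pairs` is omitted,
#' adjacent-contact pairs are proposed automatically from numeric label
#' suffixes (J1-J2, J2-J3, ...); primed labels are treated as plain text.
#'
#' @param rec a [recording()].
#' @param pairs list of length-2 character vectors `(contactA, contactB)`.
#' @return A new [recording()] of bipolar channels; metadata propagated.
#' @export
make_bipolar <- function(rec, pairs = NULL) {
  stopifnot(inherits(rec, "recording"))
  labels <- rec$channel_labels
  if (is.null(pairs)) {
    m <- regmatches(labels, regexec("^(.*?)([0-9]+)$", labels))
    pref <- vapply(m, function(g) if (length(g)) g[2] else NA_character_, "")
    num <- vapply(m, function(g) if (length(g)) as.numeric(g[3]) else NA_real_, 0)
    pairs <- list()
    for (i in seq_along(labels)) {
      if (is.na(num[i])) next
      j <- which(pref == pref[i] & num == num[i] + 1)
      if (length(j) == 1L) pairs[[length(pairs) + 1L]] <- c(labels[i], labels[j])
    }
    if (!length(pairs)) {
      abort("no adjacent contact pairs could be proposed", "acinet_invalid_argument")
    }
  }
  idx <- function(lab) {
    i <- match(lab, labels)
    if (is.na(i)) abort(sprintf("unknown contact '%s'", lab), "acinet_key_error")
    i
  }
  out <- matrix(0, nrow = length(pairs), ncol = ncol(rec$data))
  new_labels <- character(length(pairs))
  for (k in seq_along(pairs)) {
    p <- pairs[[k]]
    out[k, ] <- rec$data[idx(p[1]), ] - rec$data[idx(p[2]), ]
    new_labels[k] <- paste0(p[1], "-", p[2])
  }
  recording(out, fs = rec$fs, channel_labels = new_labels,
            region_labels = rec$region_labels, soz_flags = rec$soz_flags)
}

#' Write per-period result tables and a run summary
#'
#' Writes the period-level h2/D/E:I table as CSV and a run summary
#' (SOZ call, statistics, settings, seed, software version) as JSON with
#' deterministic field ordering. Refuses to write empty results.
#'
#' @param report a report object from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  if (is.null(report) || !inherits(report, "acin_report") ||
      is.null(report$periods) || !nrow(report$periods)) {
    abort("refusing to write an empty report", "acinet_invalid_argument")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  conn_path <- file.path(dir, "periods.csv")
  stats_path <- file.path(dir, "stats.csv")
  json_path <- file.path(dir, "summary.json")
  utils::write.csv(report$periods, conn_path, row.names = FALSE)
  utils::write.csv(report$stats, stats_path, row.names = FALSE)
  summary <- list(
    software = paste0("acinet ", as.character(utils::packageVersion("acinet"))),
    seed = report$settings$seed,
    settings = report$settings[order(names(report$settings))],
    band = report$band,
    soz_call = report$soz_call[order(names(report$soz_call))],
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(periods = conn_path, stats = stats_path, summary = json_path))
}
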