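# Minimal EDF reader/writer for continuous multichannel recordings.
# Implements the 16-bit integer European Data Format with 1-second data
# records; sufficient for round-tripping simulator output and reading
# uniform-rate clinical exports.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write a recording to an EDF file
#'
#' Continuous EDF with 1-second data records and 16-bit samples. The total
#' duration must be a whole number of seconds. Physical range defaults to
#' +/- 2000 microvolts; samples outside it are clipped.
#'
#' @param rec a [recording()].
#' @param path output file path.
#' @param physical_range symmetric physical range in microvolts (default 2000).
#' @return Invisibly, `path`.
#' @export
write_edf <- function(rec, path, physical_range = 2000) {
  stopifnot(inherits(rec, "recording"))
  n <- ncol(rec$data)
  ns <- nrow(rec$data)
  spr <- rec$fs  # samples per 1-s record
  if (spr != round(spr) || n %% spr != 0) {
    abort("EDF output needs an integer sampling rate and whole-second duration",
          "acinet_invalid_argument")
  }
  n_rec <- n / spr
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4)
  )
  field <- function(vals, width) paste(vapply(vals, edf_pad, "", width = width),
                                       collapse = "")
  hdr <- paste0(hdr,
    field(rec$channel_labels, 16),
    field(rep("", ns), 80),
    field(rep("uV", ns), 8),
    field(rep(-physical_range, ns), 8),
    field(rep(physical_range, ns), 8),
    field(rep(-32768L, ns), 8),
    field(rep(32767L, ns), 8),
    field(rep("", ns), 80),
    field(rep(spr, ns), 8),
    field(rep("", ns), 32)
  )
  writeChar(hdr, con, eos = NULL)
  gain <- (2 * physical_range) / (32767 - (-32768))
  dig <- round((pmax(pmin(rec$data, physical_range), -physical_range) +
                  physical_range) / gain) - 32768
  dig <- matrix(as.integer(pmin(pmax(dig, -32768), 32767)), nrow = ns)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con,
             size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a recording from an EDF file
#'
#' Reads continuous EDF/EDF+ with 16-bit samples. All selected channels must
#' share one sampling rate; pass `channels` to restrict to a uniform subset
#' of a mixed-rate file.
#'
#' @param path EDF file path.
#' @param channels optional character vector of channel labels to keep.
#' @return A [recording()].
#' @export
read_edf <- function(path, channels = NULL) {
  if (!is.character(path) || !nzchar(path) || !file.exists(path)) {
    abort(sprintf("EDF file not found: '%s'", path), "acinet_missing_file")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8); rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- suppressWarnings(as.integer(rd(8)))
  rd(44)
  n_rec <- suppressWarnings(as.integer(rd(8)))
  rec_dur <- suppressWarnings(as.numeric(rd(8)))
  ns <- suppressWarnings(as.integer(rd(4)))
  if (is.na(ns) || ns < 1 || is.na(n_rec) || is.na(rec_dur) || rec_dur <= 0 ||
      is.na(hdr_bytes) || hdr_bytes != 256 * (1 + ns)) {
    abort("corrupt or unsupported EDF header", "acinet_corrupt_header")
  }
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)              # transducer
  units <- vapply(seq_len(ns), function(i) rd(8), "")
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)              # prefilter
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (anyNA(c(pmin_, pmax_, dmin_, dmax_, spr))) {
    abort("corrupt or unsupported EDF header", "acinet_corrupt_header")
  }
  keep <- seq_len(ns)
  if (!is.null(channels)) {
    keep <- match(channels, labels)
    if (anyNA(keep)) {
      abort("requested channel(s) not present in EDF", "acinet_key_error")
    }
  }
  if (length(unique(spr[keep])) != 1L) {
    abort("channels have mixed sampling rates; select a uniform subset",
          "acinet_mixed_rate")
  }
  raw <- vector("list", length(keep))
  for (k in seq_along(keep)) raw[[k]] <- numeric(n_rec * spr[keep[k]])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      vals <- readBin(con, integer(), n = spr[i], size = 2,
                      signed = TRUE, endian = "little")
      k <- match(i, keep)
      if (!is.na(k)) {
        raw[[k]][((r - 1) * spr[i] + 1):(r * spr[i])] <- vals
      }
    }
  }
  data <- matrix(0, nrow = length(keep), ncol = n_rec * spr[keep[1]])
  for (k in seq_along(keep)) {
    i <- keep[k]
    gain <- (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i])
    data[k, ] <- (raw[[k]] - dmin_[i]) * gain + pmin_[i]
  }
  fs <- spr[keep[1]] / rec_dur
  recording(data, fs = fs, channel_labels = labels[keep])
}
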