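# Minimal European Data Format (EDF) support: 16-bit standard EDF with one
# data record per second. Covers the subset of the format that multichannel
# iEEG interchange needs (equal sampling rate on all signals, no annotations).

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Write / read a recording as a standard EDF file
#'
#' Signals are scaled channel-wise to the full 16-bit digital range; the
#' physical min/max stored in the header make the round trip exact to about
#' 5 decimal digits. The sampling rate must be a whole number and the
#' recording is truncated to a whole number of 1-second data records.
#'
#' @param rec a [recording()].
#' @param path output path.
#' @return `write_recording_edf()` returns `path` invisibly;
#'   `read_recording_edf()` returns a [recording()] (groups, which EDF cannot
#'   carry, are taken from `groups_file` when given).
#' @export
write_recording_edf <- function(rec, path) {
  stopifnot(inherits(rec, "miso_recording"))
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  ns <- n_channels(rec)
  n_rec <- floor(n_samples(rec) / fs)
  if (n_rec < 1L) stop("recording shorter than one 1-second data record")
  x <- rec$samples[, seq_len(n_rec * fs), drop = FALSE]

  pmin <- apply(x, 1L, min); pmax <- apply(x, 1L, max)
  flat <- pmax - pmin < .Machine$double.eps
  pmax[flat] <- pmin[flat] + 1
  dmin <- -32768; dmax <- 32767
  # digital = (physical - pmin) / (pmax - pmin) * (dmax - dmin) + dmin
  dig <- round((x - pmin) / (pmax - pmin) * (dmax - dmin) + dmin)
  storage.mode(dig) <- "integer"

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(edf_pad(s, w), con, nchars = w, eos = NULL)
  wr("0", 8)
  wr("X X X X", 80)
  wr("Startdate 01-JAN-2000 X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256L * (ns + 1L), 8)
  wr("", 44)
  wr(n_rec, 8)
  wr("1", 8)
  wr(ns, 4)
  for (lab in rec$channel_labels) wr(lab, 16)
  for (i in seq_len(ns)) wr("", 80)                       # transducer
  for (i in seq_len(ns)) wr("uV", 8)                      # physical dimension
  for (i in seq_len(ns)) wr(formatC(pmin[i], digits = 7, format = "g"), 8)
  for (i in seq_len(ns)) wr(formatC(pmax[i], digits = 7, format = "g"), 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)                       # prefiltering
  for (i in seq_len(ns)) wr(fs, 8)                        # samples per record
  for (i in seq_len(ns)) wr("", 32)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (k in seq_len(ns))
      writeBin(dig[k, idx], con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' @rdname write_recording_edf
#' @param groups_file optional channel-group file, see [read_channel_groups()].
#' @export
read_recording_edf <- function(path, groups_file = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L)
    stop("EDF reader supports a single sampling rate across signals")
  fs <- spr[1L] / rec_dur
  x <- matrix(0, ns, n_rec * spr[1L])
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr[1L] + 1L):(r * spr[1L])
    for (k in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[1L], size = 2L, signed = TRUE,
                   endian = "little")
      x[k, idx] <- (d - dmin[k]) / (dmax[k] - dmin[k]) *
        (pmax[k] - pmin[k]) + pmin[k]
    }
  }
  groups <- if (!is.null(groups_file)) read_channel_groups(groups_file) else NULL
  recording(x, fs = fs, channel_labels = labels, groups = groups)
}
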