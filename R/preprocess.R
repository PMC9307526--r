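#' Zero-phase 60 Hz notch filter
#'
#' Applies a second-order IIR notch (quality factor 30) forward and backward
#' to every channel, removing mains interference without phase distortion.
#'
#' @param rec a [recording()].
#' @param freq notch centre frequency in Hz; must be below Nyquist.
#' @param q quality factor (centre frequency / -3 dB bandwidth).
#' @return A filtered [recording()] of identical shape.
#' @export
notch_filter <- function(rec, freq = 60, q = 30) {
  stopifnot(inherits(rec, "miso_recording"))
  if (freq >= rec$fs / 2) stop("notch frequency must be below Nyquist")
  w0 <- 2 * pi * freq / rec$fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  b <- b / a[1L]; a <- a / a[1L]
  apply_filtfilt(rec, b, a)
}

# Analog Butterworth prototype poles realized as digital second-order
# sections via the bilinear transform; cascading SOS keeps high orders
# numerically stable at very low normalized cutoffs, where the expanded
# transfer-function form of a 10th-order filter breaks down.
butter_sos <- function(order, cutoff_hz, fs, type = c("high", "low")) {
  type <- match.arg(type)
  if (order %% 2L != 0L) stop("even filter order required for SOS cascade")
  wc <- 2 * fs * tan(pi * cutoff_hz / fs)   # prewarped analog cutoff (rad/s)
  k <- seq_len(order / 2L)
  theta <- pi * (2 * k - 1) / (2 * order)
  sos <- lapply(theta, function(th) {
    # conjugate analog pole pair: s^2 + 2 sin(th) wc s + wc^2 (lowpass);
    # highpass by s -> wc^2 / s, which maps onto the same denominator with
    # numerator s^2.
    a2 <- 1; a1 <- 2 * sin(th) * wc; a0 <- wc^2
    if (type == "low") { b2 <- 0; b1 <- 0; b0 <- wc^2 } else { b2 <- 1; b1 <- 0; b0 <- 0 }
    # bilinear transform s = 2 fs (z-1)/(z+1)
    K <- 2 * fs
    A0 <- a2 * K^2 + a1 * K + a0
    A1 <- 2 * a0 - 2 * a2 * K^2
    A2 <- a2 * K^2 - a1 * K + a0
    B0 <- b2 * K^2 + b1 * K + b0
    B1 <- 2 * b0 - 2 * b2 * K^2
    B2 <- b2 * K^2 - b1 * K + b0
    list(b = c(B0, B1, B2) / A0, a = c(1, A1 / A0, A2 / A0))
  })
  sos
}

apply_filtfilt <- function(rec, b, a) {
  out <- t(apply(rec$samples, 1L, function(x) signal::filtfilt(b, a, x)))
  recording(out, fs = rec$fs, channel_labels = rec$channel_labels,
            groups = rec$groups)
}

#' Zero-phase Butterworth band-pass filter
#'
#' A 10th-order (by default) Butterworth band-pass applied forward and
#' backward per channel. When the upper edge reaches or exceeds Nyquist --
#' as with the conventional 0.5-256 Hz band at a 512 Hz sampling rate -- the
#' band edge is ill-posed and the filter degrades to the high-pass branch
#' alone; this is reported via a message and the `"degraded_to_highpass"`
#' attribute of the result.
#'
#' @param rec a [recording()].
#' @param low,high band edges in Hz.
#' @param order Butterworth design order (before forward-backward doubling).
#' @return A filtered [recording()].
#' @export
bandpass_filter <- function(rec, low = 0.5, high = 256, order = 10) {
  stopifnot(inherits(rec, "miso_recording"))
  nyq <- rec$fs / 2
  if (low >= nyq) stop("low edge at or above Nyquist")
  if (low >= high) stop("low edge must be below high edge")
  degraded <- high >= nyq
  if (degraded)
    message(sprintf(
      "band-pass upper edge %g Hz >= Nyquist (%g Hz): applying %d-th order high-pass at %g Hz only",
      high, nyq, order, low))
  out <- rec
  for (sec in butter_sos(order, low, rec$fs, "high"))
    out <- apply_filtfilt(out, sec$b, sec$a)
  if (!degraded) {
    for (sec in butter_sos(order, high, rec$fs, "low"))
      out <- apply_filtfilt(out, sec$b, sec$a)
  }
  attr(out, "degraded_to_highpass") <- degraded
  out
}

#' Common average reference
#'
#' Subtracts, at every sample, the instantaneous mean across all channels
#' (common average montage). Requires at least two channels.
#'
#' @param rec a [recording()].
#' @return A re-referenced [recording()]; per-sample channel means are zero
#'   to numerical tolerance.
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "miso_recording"))
  if (n_channels(rec) < 2L)
    stop("common average reference undefined for a single channel")
  out <- sweep(rec$samples, 2L, colMeans(rec$samples))
  recording(out, fs = rec$fs, channel_labels = rec$channel_labels,
            groups = rec$groups)
}

#' Default preprocessing chain
#'
#' Notch at 60 Hz, 0.5-256 Hz Butterworth band-pass (order 10), common
#' average reference -- in that order.
#'
#' @param rec a [recording()].
#' @return A preprocessed [recording()].
#' @export
preprocess_recording <- function(rec) {
  common_average_reference(
    suppressMessages(bandpass_filter(notch_filter(rec))))
}

#' Sliding-window epoching relative to seizure onset
#'
#' Splits the span seconds before `onset` into `span / step` overlapping
#' windows of `window` seconds advanced by `step` seconds. Epoch `i` *ends*
#' at `onset - span + i * step` seconds, so the default 120 s span yields
#' 120 ten-second epochs ending at -119, -118, ..., 0 s relative to onset;
#' the recording must therefore cover `span + window` seconds before onset.
#' No window extends past onset.
#'
#' @param rec a [recording()].
#' @param onset seizure onset in seconds from the start of the recording.
#' @param span analysed pre-onset span in seconds.
#' @param window epoch length in seconds.
#' @param step window advance in seconds.
#' @return A list of epochs; each has `samples` (channels x window samples),
#'   `start_time`/`end_time` in seconds relative to onset, `index`, `fs`,
#'   `channel_labels`, and `groups`.
#' @export
epoch_sliding <- function(rec, onset, span = 120, window = 10, step = 1) {
  stopifnot(inherits(rec, "miso_recording"))
  fs <- rec$fs
  # epoch 1 starts at onset - span + step - window, which must lie within
  # the recording: span + window - step seconds of pre-onset data required
  if (onset - span - window + step < 0)
    stop(sprintf("insufficient pre-onset data: need %g s before onset, onset at %g s",
                 span + window - step, onset))
  if (round(onset * fs) > n_samples(rec))
    stop("onset lies beyond the end of the recording")
  n_ep <- round(span / step)
  wlen <- round(window * fs)
  lapply(seq_len(n_ep), function(i) {
    end_t <- -span + i * step                 # seconds relative to onset
    end_idx <- round((onset + end_t) * fs)
    idx <- (end_idx - wlen + 1L):end_idx
    structure(
      list(samples = rec$samples[, idx, drop = FALSE],
           start_time = end_t - window, end_time = end_t, index = i,
           fs = fs, channel_labels = rec$channel_labels,
           groups = rec$groups),
      class = "miso_epoch")
  })
}

#' Treat a whole recording as a single analysis epoch
#'
#' Convenience wrapper for static (single-window) analyses such as
#' stationary benchmark recordings: wraps the full sample matrix in the
#' epoch structure used by the model-fitting functions.
#'
#' @param rec a [recording()].
#' @param index epoch index to assign.
#' @return A `"miso_epoch"`.
#' @export
as_epoch <- function(rec, index = 1L) {
  stopifnot(inherits(rec, "miso_recording"))
  structure(
    list(samples = rec$samples, start_time = -ncol(rec$samples) / rec$fs,
         end_time = 0, index = as.integer(index), fs = rec$fs,
         channel_labels = rec$channel_labels, groups = rec$groups),
    class = "miso_epoch")
}

#' @export
print.miso_epoch <- function(x, ...) {
  cat(sprintf("<miso_epoch #%d> %d ch x %d samples, [%g, %g] s rel. onset\n",
              x$index, nrow(x$samples), ncol(x$samples),
              x$start_time, x$end_time))
  invisible(x)
}
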