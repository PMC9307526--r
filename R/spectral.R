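#' Canonical EEG frequency bands
#'
#' Delta < 4 Hz, theta 4-7 Hz, alpha 8-13 Hz, beta 13-25 Hz, and gamma
#' 25-55 Hz. The gamma limits are a package choice (the band is
#' conventional only up to its lower edge at the end of beta): the top is
#' capped at 55 Hz to stay clear of the 60 Hz notch-filtered region.
#'
#' @return Data frame with columns `name`, `low`, `high` (Hz); each band
#'   covers `[low, high)`.
#' @export
canonical_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             low  = c(0.5, 4,  8, 13, 25),
             high = c(4,   7, 13, 25, 55),
             stringsAsFactors = FALSE)
}

#' Welch power spectral density
#'
#' Averaged modified periodograms: Hann-tapered segments of
#' `segment_seconds` with 50% overlap, one-sided density normalized so that
#' `sum(psd) * df` equals the signal's mean squared amplitude (Parseval).
#'
#' @param x numeric signal vector.
#' @param fs sampling rate in Hz.
#' @param segment_seconds segment length in seconds.
#' @param overlap fractional overlap between segments.
#' @return List with `freq` (Hz) and `psd` (signal-units^2 per Hz).
#' @export
welch_psd <- function(x, fs, segment_seconds = 2, overlap = 0.5) {
  nseg <- round(segment_seconds * fs)
  if (nseg > length(x)) nseg <- length(x)
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))   # Hann taper
  U <- sum(w^2)
  nf <- floor(nseg / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)] * w
    P <- Mod(stats::fft(seg))^2 / (U * fs)
    acc <- acc + P[seq_len(nf)]
  }
  psd <- acc / length(starts)
  # fold two-sided density into one-sided (all bins except DC and Nyquist)
  inner <- 2:(nf - if (nseg %% 2L == 0L) 1L else 0L)
  psd[inner] <- 2 * psd[inner]
  list(freq = (seq_len(nf) - 1L) * fs / nseg, psd = psd)
}

#' Band power of a single-channel signal
#'
#' Integrates the Welch power spectral density over `[low, high)`.
#'
#' @param x numeric signal vector (one channel, one epoch).
#' @param fs sampling rate in Hz.
#' @param band either a band name from [canonical_bands()] or a
#'   `c(low, high)` pair in Hz; must lie inside `(0, fs/2)`.
#' @param segment_seconds,overlap Welch parameters, see [welch_psd()].
#' @return Band power in signal-units squared.
#' @export
band_power <- function(x, fs, band, segment_seconds = 2, overlap = 0.5) {
  if (is.character(band)) {
    bands <- canonical_bands()
    row <- bands[bands$name == band, ]
    if (nrow(row) != 1L) stop("unknown band name: ", band)
    band <- c(row$low, row$high)
  }
  stopifnot(length(band) == 2L, band[1L] < band[2L])
  if (band[2L] > fs / 2) stop("band extends beyond Nyquist")
  if (band[1L] <= 0) stop("band must start above 0 Hz")
  sp <- welch_psd(x, fs, segment_seconds, overlap)
  sel <- sp$freq >= band[1L] & sp$freq < band[2L]
  df <- sp$freq[2L] - sp$freq[1L]
  sum(sp$psd[sel]) * df
}

#' Mean log band power per channel group and network state
#'
#' Computes log10 band power for every (channel, epoch), then averages
#' within each (group, band, state) cell of the segmentation. Epochs with
#' zero power in a band are excluded from the log average and counted.
#'
#' @param epochs list of epochs from [epoch_sliding()].
#' @param groups named group vector label -> SOZ/PSZ/NSZ.
#' @param segmentation a [segment_states()] result covering the epochs, or
#'   a character vector of per-epoch state labels.
#' @param bands band definition data frame (default [canonical_bands()]).
#' @return Data frame: `group`, `band`, `state`, `mean_log_power`, `sd`,
#'   `n`, `n_zero_power`.
#' @export
band_power_by_state <- function(epochs, groups, segmentation,
                                bands = canonical_bands()) {
  state <- if (inherits(segmentation, "miso_segmentation"))
    segmentation$state else as.character(segmentation)
  if (length(state) != length(epochs))
    stop("segmentation does not cover the epochs")
  labels <- epochs[[1L]]$channel_labels
  groups <- validate_groups(groups, labels)
  fs <- epochs[[1L]]$fs
  # one Welch PSD per (channel, epoch), integrated over each band
  power <- lapply(epochs, function(ep)
    apply(ep$samples, 1L, function(x) {
      sp <- welch_psd(x, fs)
      df <- sp$freq[2L] - sp$freq[1L]
      vapply(seq_len(nrow(bands)), function(bi)
        sum(sp$psd[sp$freq >= bands$low[bi] & sp$freq < bands$high[bi]]) * df,
        0)
    }))                                      # each: bands x channels
  rows <- list()
  for (bi in seq_len(nrow(bands))) {
    bp <- vapply(power, function(p) p[bi, ], numeric(length(labels)))
    for (g in c("SOZ", "PSZ", "NSZ")) {
      for (st in unique(state)) {
        v <- as.numeric(bp[groups == g, state == st])
        zero <- v <= 0
        lg <- log10(v[!zero])
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, band = bands$name[bi], state = st,
          mean_log_power = if (length(lg)) mean(lg) else NA_real_,
          sd = if (length(lg) > 1L) stats::sd(lg) else 0,
          n = length(lg), n_zero_power = sum(zero),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
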