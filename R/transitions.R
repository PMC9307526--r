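#' Detect a centrality state transition by the one-standard-deviation rule
#'
#' Computes the mean and standard deviation of the series over the baseline
#' epochs and returns the first later epoch whose value strictly exceeds
#' mean + SD (by default requiring a single exceedance; `persist` demands
#' that many consecutive exceedances for noise robustness). With a constant
#' baseline (SD = 0) any strict increase above the baseline mean triggers --
#' the documented degenerate behaviour.
#'
#' @param series numeric per-epoch values (group-mean centrality).
#' @param baseline_epochs indices of the baseline range; must precede the
#'   search range.
#' @param search_epochs indices to scan (default: everything after the
#'   baseline range).
#' @param persist number of consecutive exceedances required.
#' @return The transition epoch index, or `NA` if never exceeded. The
#'   baseline mean and SD are attached as attributes.
#' @export
detect_transition <- function(series, baseline_epochs,
                              search_epochs = NULL, persist = 1) {
  stopifnot(length(baseline_epochs) >= 1, persist >= 1)
  if (is.null(search_epochs))
    search_epochs <- seq(max(baseline_epochs) + 1L, length(series))
  if (length(search_epochs) == 0L || min(search_epochs) <= max(baseline_epochs))
    stop("search range must be nonempty and follow the baseline range")
  mu <- mean(series[baseline_epochs])
  sigma <- if (length(baseline_epochs) > 1L)
    stats::sd(series[baseline_epochs]) else 0
  exceed <- series[search_epochs] > mu + sigma
  hit <- NA_integer_
  run <- 0L
  for (i in seq_along(exceed)) {
    run <- if (isTRUE(exceed[i])) run + 1L else 0L
    if (run >= persist) { hit <- search_epochs[i - persist + 1L]; break }
  }
  structure(hit, baseline_mean = mu, baseline_sd = sigma)
}

# Expanding-baseline scan: for each candidate epoch the baseline is every
# epoch of the current state up to the candidate, frozen once the rule
# fires ("1 SD above the previous state value", the previous state being
# the whole preceding period).
expanding_detect <- function(series, start, min_baseline = 10, persist = 1,
                             end = length(series)) {
  first_candidate <- start + min_baseline
  if (first_candidate > end) return(structure(NA_integer_,
                                              baseline_mean = NA_real_,
                                              baseline_sd = NA_real_))
  run <- 0L
  for (e in first_candidate:end) {
    base <- start:(e - run - 1L)
    mu <- mean(series[base]); sigma <- stats::sd(series[base])
    if (series[e] > mu + sigma) run <- run + 1L else run <- 0L
    if (run >= persist) {
      base <- start:(e - run)   # baseline frozen at the first exceedance
      return(structure(e - run + 1L,
                       baseline_mean = mean(series[base]),
                       baseline_sd = stats::sd(series[base])))
    }
  }
  structure(NA_integer_, baseline_mean = NA_real_, baseline_sd = NA_real_)
}

#' Segment the preictal record into the three network states
#'
#' The first transition (isolated SOZ hyperconnectivity) is detected on the
#' SOZ group-mean centrality series with an expanding baseline from the
#' start of the record; the second (preictal recruitment) on the pooled
#' PSZ+NSZ series using the epochs between the two transitions as its
#' baseline. Epochs are labeled `Interictal`, `SOZ_delta`, `PSZ_NSZ_delta`.
#'
#' @param soz_series,psz_series,nsz_series aligned per-epoch group-mean
#'   centrality series of equal length.
#' @param metric which metric the series carry (`"BC"` default, or `"DC"`);
#'   recorded in the result.
#' @param span,step epoching parameters used to convert epoch indices to
#'   seconds before onset (epoch `i` ends at `-span + i * step` s).
#' @param min_baseline_first minimum number of interictal baseline epochs
#'   before the first transition can fire. The default (one third of the
#'   120-epoch record) is long enough for the baseline SD to reflect the
#'   bursty epoch-to-epoch variability that overlapping sliding windows
#'   produce; the interictal state is expected to persist for well over
#'   this span.
#' @param min_baseline_second minimum number of SOZ-state epochs before the
#'   second transition can fire. The state between the two transitions is
#'   short (about 30 epochs) and its first third still carries windows that
#'   straddle the first transition, whose models are often rejected; the
#'   default skips that settling span so a rejection dip and recovery is
#'   not mistaken for the second transition.
#' @param persist consecutive exceedances required (see
#'   [detect_transition()]); used for both transitions unless overridden.
#' @param persist_first,persist_second per-transition overrides. The final
#'   state is short (about 10 epochs), so its persistence requirement must
#'   stay small enough for a run to fit before the record ends.
#' @param psz_weight,nsz_weight weights for pooling the PSZ and NSZ series
#'   (defaults: equal).
#' @return Object of class `"miso_segmentation"`: `t_soz_delta` and
#'   `t_recruit` (seconds before onset, negative; `NA` if not found),
#'   transition epoch indices, per-epoch `state` labels, baseline
#'   statistics, and `metric_used`.
#' @export
segment_states <- function(soz_series, psz_series, nsz_series,
                           metric = c("BC", "DC"), span = 120, step = 1,
                           min_baseline_first = 40, min_baseline_second = 20,
                           persist = 1, persist_first = persist,
                           persist_second = persist,
                           psz_weight = 0.5, nsz_weight = 0.5) {
  metric <- match.arg(metric)
  n <- length(soz_series)
  stopifnot(length(psz_series) == n, length(nsz_series) == n)
  pooled <- (psz_weight * psz_series + nsz_weight * nsz_series) /
    (psz_weight + nsz_weight)
  t1 <- expanding_detect(soz_series, 1L, min_baseline_first, persist_first)
  t2 <- structure(NA_integer_, baseline_mean = NA_real_, baseline_sd = NA_real_)
  if (!is.na(t1) && t1 + min_baseline_second <= n)
    t2 <- expanding_detect(pooled, as.integer(t1), min_baseline_second,
                           persist_second)
  state <- rep("Interictal", n)
  if (!is.na(t1)) state[seq(t1, n)] <- "SOZ_delta"
  valid <- TRUE
  if (!is.na(t2)) {
    if (is.na(t1) || t2 <= t1) valid <- FALSE
    else state[seq(t2, n)] <- "PSZ_NSZ_delta"
  }
  to_time <- function(i) if (is.na(i)) NA_real_ else -span + as.numeric(i) * step
  structure(
    list(t_soz_delta = to_time(t1), t_recruit = to_time(t2),
         epoch_soz_delta = as.integer(t1), epoch_recruit = as.integer(t2),
         baseline_mean = attr(t1, "baseline_mean"),
         baseline_sd = attr(t1, "baseline_sd"),
         soz_state_mean = attr(t2, "baseline_mean"),
         soz_state_sd = attr(t2, "baseline_sd"),
         state = state, metric_used = metric, valid = valid,
         span = span, step = step),
    class = "miso_segmentation")
}

#' @export
print.miso_segmentation <- function(x, ...) {
  cat(sprintf("<miso_segmentation> (%s) SOZ delta at %s s, recruitment at %s s%s\n",
              x$metric_used,
              if (is.na(x$t_soz_delta)) "-" else format(x$t_soz_delta),
              if (is.na(x$t_recruit)) "-" else format(x$t_recruit),
              if (x$valid) "" else " [INVALID ORDER]"))
  invisible(x)
}

#' Aggregate per-seizure transition times
#'
#' @param times numeric vector of per-seizure transition times (seconds,
#'   negative before onset); `NA`s are dropped and counted.
#' @return List with `mean`, `sd` (sample SD; 0 with a `single` flag when
#'   only one time is available), `median`, `n`, `n_missing`.
#' @export
aggregate_transitions <- function(times) {
  n_missing <- sum(is.na(times))
  times <- times[!is.na(times)]
  if (length(times) == 0L) stop("no transition times to aggregate")
  list(mean = mean(times),
       sd = if (length(times) > 1L) stats::sd(times) else 0,
       median = stats::median(times),
       n = length(times), n_missing = n_missing,
       single = length(times) == 1L)
}
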