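#' Multichannel iEEG recording
#'
#' A `Recording` bundles a channels-by-samples signal matrix with its sampling
#' rate, channel labels, and the SOZ/PSZ/NSZ group assignment of every
#' channel. Row `k` of `samples` holds the time series \eqn{y_k(t)} of
#' channel `k` in microvolts (by convention).
#'
#' @param samples numeric matrix, channels in rows, samples in columns.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector of unique channel names, one per row.
#' @param groups named character vector mapping every label to one of
#'   `"SOZ"`, `"PSZ"`, `"NSZ"`, or `NULL` when no assignment is available.
#'
#' @return An object of class `"miso_recording"` with fields `samples`, `fs`,
#'   `channel_labels`, `groups`.
#' @export
recording <- function(samples, fs, channel_labels = NULL, groups = NULL) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!all(is.finite(samples)))
    stop("recording contains non-finite samples (NaN/Inf)")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  n <- nrow(samples)
  if (is.null(channel_labels))
    channel_labels <- sprintf("ch%02d", seq_len(n))
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != n)
    stop("need one label per channel row")
  if (anyDuplicated(channel_labels))
    stop("channel labels must be unique")
  if (!is.null(groups)) {
    groups <- validate_groups(groups, channel_labels)
  }
  rownames(samples) <- channel_labels
  structure(
    list(samples = samples, fs = fs, channel_labels = channel_labels,
         groups = groups),
    class = "miso_recording")
}

validate_groups <- function(groups, channel_labels) {
  groups <- unlist(groups)
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be a named vector: label -> SOZ/PSZ/NSZ")
  bad <- setdiff(groups, c("SOZ", "PSZ", "NSZ"))
  if (length(bad))
    stop("unknown group label(s): ", paste(unique(bad), collapse = ", "))
  missing <- setdiff(channel_labels, names(groups))
  if (length(missing))
    stop("channels without group assignment: ", paste(missing, collapse = ", "))
  groups[channel_labels]
}

#' @export
print.miso_recording <- function(x, ...) {
  cat(sprintf("<miso_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs))
  if (!is.null(x$groups))
    cat("  groups:", paste(sprintf("%s=%d", names(table(x$groups)),
                                   table(x$groups)), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.miso_recording <- function(x) dim(x$samples)

n_channels <- function(rec) nrow(rec$samples)
n_samples  <- function(rec) ncol(rec$samples)

#' Read and write recordings as a delimited matrix plus sidecar header
#'
#' The text format is a tab-separated numeric matrix (one row per channel,
#' no header row) accompanied by a YAML sidecar `<file>.yaml` with the
#' sampling rate, channel labels, and (optionally) the SOZ/PSZ/NSZ group of
#' each channel.
#'
#' @param rec a [recording()].
#' @param path path of the matrix file; the sidecar is written at
#'   `paste0(path, ".yaml")`.
#' @return `write_recording_text()` returns `path` invisibly;
#'   `read_recording_text()` returns a [recording()].
#' @export
write_recording_text <- function(rec, path) {
  stopifnot(inherits(rec, "miso_recording"))
  utils::write.table(rec$samples, file = path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  hdr <- list(fs = rec$fs, channel_labels = as.list(rec$channel_labels))
  if (!is.null(rec$groups))
    hdr$groups <- as.list(stats::setNames(as.character(rec$groups),
                                          names(rec$groups)))
  yaml::write_yaml(hdr, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_recording_text
#' @param groups_file optional two-column text file (label, group) overriding
#'   any groups in the sidecar.
#' @export
read_recording_text <- function(path, groups_file = NULL) {
  hdr_path <- paste0(path, ".yaml")
  if (!file.exists(hdr_path))
    stop("sidecar header not found: ", hdr_path)
  hdr <- yaml::read_yaml(hdr_path)
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  labels <- unlist(hdr$channel_labels)
  groups <- if (!is.null(hdr$groups)) unlist(hdr$groups) else NULL
  if (!is.null(groups_file)) groups <- read_channel_groups(groups_file)
  recording(m, fs = hdr$fs, channel_labels = labels, groups = groups)
}

#' Read a channel-group assignment file
#'
#' Two whitespace- or comma-separated columns: channel label and group
#' (`SOZ`, `PSZ` or `NSZ`). Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return named character vector label -> group.
#' @export
read_channel_groups <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE,
                           sep = if (grepl("\\.csv$", path)) "," else "")
  if (ncol(tab) < 2L) stop("groups file needs two columns: label, group")
  stats::setNames(trimws(as.character(tab[[2L]])),
                  trimws(as.character(tab[[1L]])))
}
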