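#' Scenario configuration for the synthetic iEEG generator
#'
#' Describes a piecewise-stationary vector-autoregressive (VAR) ground-truth
#' scenario emulating the preictal network-state sequence: a low, dense
#' baseline coupling; a step increase of SOZ-internal directed coupling at
#' `t_soz_delta` seconds before onset; and a later step increase of
#' SOZ-to-PSZ/NSZ outgoing coupling at `t_recruit` seconds before onset,
#' on a pink-noise background.
#'
#' @param n_channels number of channels.
#' @param fs sampling rate in Hz.
#' @param duration recording length in seconds (the recording ends at onset).
#' @param group_assignment named character vector label -> SOZ/PSZ/NSZ, or
#'   `NULL` for an automatic split (about a quarter SOZ, a quarter PSZ).
#' @param onset_time seizure-onset reference in seconds; equals the end of
#'   the generated span.
#' @param t_soz_delta,t_recruit step times in seconds *before* onset; must
#'   satisfy `t_soz_delta > t_recruit > 0`.
#' @param baseline_coupling dimensionless gain applied to every directed
#'   channel pair in the baseline phase.
#' @param n_backbone number of stable strong background edges ("backbone").
#'   Interictal iEEG networks are not flat: they show sparse, persistent
#'   connection clusters, emulated by a few randomly placed (seeded) strong
#'   edges between non-SOZ channels. Keeping both endpoints outside the SOZ
#'   means neither coupling step alters them and, crucially, they cannot
#'   close strong feedback cycles with the planted SOZ-source couplings
#'   (cycle gain enters the process spectral radius, so a backbone edge
#'   into the SOZ would destabilize the recruitment phase).
#' @param backbone_coupling strength of each backbone edge.
#' @param soz_gain multiplicative gain on SOZ->SOZ couplings after the first
#'   step.
#' @param recruit_gain multiplicative gain on SOZ->PSZ and SOZ->NSZ couplings
#'   after the second step.
#' @param var_order lag order of the generative VAR process.
#' @param noise_sd innovation standard deviation (signal units).
#' @param pink_noise_fraction fraction of innovation variance carried by
#'   1/f-shaped (pink) noise, in `[0, 1]`.
#' @param soz_delta_drive amplitude of an additional 2 Hz (delta-band)
#'   oscillation added to SOZ channels only; 0 disables it.
#' @param seed integer seed; identical seeds give bit-identical recordings.
#'
#' @return A list of class `"miso_scenario"`.
#' @export
scenario_config <- function(n_channels = 12, fs = 512, duration = 140,
                            group_assignment = NULL, onset_time = duration,
                            t_soz_delta = 40, t_recruit = 10,
                            baseline_coupling = 0.01, soz_gain = 30,
                            recruit_gain = 28, n_backbone = 3,
                            backbone_coupling = 0.25, var_order = 3,
                            noise_sd = 1, pink_noise_fraction = 0.05,
                            soz_delta_drive = 0, seed = 1) {
  stopifnot(n_channels >= 3, fs > 0, duration > 0, var_order >= 1,
            noise_sd > 0, pink_noise_fraction >= 0, pink_noise_fraction <= 1,
            baseline_coupling >= 0, soz_gain >= 0, recruit_gain >= 0)
  if (!(t_soz_delta > t_recruit && t_recruit > 0))
    stop("need t_soz_delta > t_recruit > 0 (both counted back from onset)")
  if (t_soz_delta >= duration)
    stop("first coupling step predates the recording")
  labels <- sprintf("ch%02d", seq_len(n_channels))
  if (is.null(group_assignment)) {
    n_soz <- max(1L, round(n_channels / 4))
    n_psz <- max(1L, round(n_channels / 4))
    grp <- c(rep("SOZ", n_soz), rep("PSZ", n_psz),
             rep("NSZ", n_channels - n_soz - n_psz))
    group_assignment <- stats::setNames(grp, labels)
  } else {
    labels <- names(group_assignment)
    if (is.null(labels)) stop("group_assignment must be a named vector")
    if (length(group_assignment) != n_channels)
      stop("group_assignment length must equal n_channels")
  }
  group_assignment <- validate_groups(group_assignment, labels)
  if (!all(c("SOZ", "PSZ", "NSZ") %in% group_assignment))
    stop("every group (SOZ, PSZ, NSZ) needs at least one channel")
  stopifnot(n_backbone >= 0, backbone_coupling >= 0)
  structure(
    list(n_channels = n_channels, fs = fs, duration = duration,
         channel_labels = labels, group_assignment = group_assignment,
         onset_time = onset_time, t_soz_delta = t_soz_delta,
         t_recruit = t_recruit, baseline_coupling = baseline_coupling,
         soz_gain = soz_gain, recruit_gain = recruit_gain,
         n_backbone = as.integer(n_backbone),
         backbone_coupling = backbone_coupling,
         var_order = var_order, noise_sd = noise_sd,
         pink_noise_fraction = pink_noise_fraction,
         soz_delta_drive = soz_delta_drive, seed = as.integer(seed)),
    class = "miso_scenario")
}

# Self-dynamics of each channel (same for every channel and phase) and the
# distribution of the cross-coupling over lags. The AR part gives a stable,
# broadband spectrum. Cross-coupling acts at lag 1 only, so an edge's
# ground-truth coupling equals the Euclidean norm of its lag-coefficient
# vector -- the quantity the estimator reports -- with no lag-splitting
# shrinkage.
var_self_coef  <- function(p) c(0.30, -0.08, 0.02, rep(0, max(0, p - 3)))[seq_len(p)]
var_lag_weight <- function(p) c(1, rep(0, p - 1L))

var_coef_list <- function(W, p) {
  a <- var_self_coef(p); g <- var_lag_weight(p)
  lapply(seq_len(p), function(l) {
    Phi <- g[l] * W
    diag(Phi) <- a[l]
    Phi
  })
}

# Evaluate `expr` under a temporary seed, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

companion_radius <- function(Phi) {
  p <- length(Phi); n <- nrow(Phi[[1L]])
  Cmp <- matrix(0, n * p, n * p)
  for (l in seq_len(p)) Cmp[seq_len(n), ((l - 1L) * n + 1L):(l * n)] <- Phi[[l]]
  if (p > 1L)
    Cmp[(n + 1L):(n * p), seq_len(n * (p - 1L))] <- diag(n * (p - 1L))
  max(Mod(eigen(Cmp, only.values = TRUE)$values))
}

# Shrink off-diagonal coupling until the companion matrix is comfortably
# stable; returns the (possibly rescaled) matrix and the factor applied.
stabilize_phase <- function(W, p, phase_name, rho_max = 0.98) {
  scale <- 1
  for (i in 1:60) {
    Ws <- W * scale
    diag(Ws) <- 0
    rho <- companion_radius(var_coef_list(Ws, p))
    if (rho < rho_max) return(list(W = Ws, scale = scale, rho = rho))
    scale <- scale * 0.85
  }
  stop("phase '", phase_name, "' cannot be stabilized by rescaling coupling")
}

#' Build the three phase coupling matrices of a scenario
#'
#' Entry `(k, j)` of each matrix is the directed coupling from source channel
#' `j` to target channel `k`; diagonals are zero. The SOZ-delta phase differs
#' from baseline only on SOZ->SOZ entries; the recruitment phase additionally
#' on SOZ->(PSZ or NSZ) entries. Any phase whose companion matrix would be
#' unstable is rescaled (factor recorded in `$rescale`).
#'
#' @param config a [scenario_config()].
#' @return A list of class `"miso_ground_truth"`: `phase_adjacency` (named
#'   list of three matrices), `planted_edges` (per-phase data frames),
#'   `phase_boundaries` (epoch indices of the two transitions under the
#'   default 120 s / 10 s / 1 s epoching), `rescale`, and the `config`.
#' @export
build_phase_networks <- function(config) {
  stopifnot(inherits(config, "miso_scenario"))
  n <- config$n_channels; g <- config$group_assignment
  soz <- g == "SOZ"
  W1 <- matrix(config$baseline_coupling, n, n); diag(W1) <- 0
  if (config$n_backbone > 0L && config$backbone_coupling > 0) {
    # seeded draw in a local RNG stream so that standalone calls and calls
    # from simulate_recording() see the same backbone; the last backbone
    # edge is afferent (non-SOZ source into a SOZ target, slightly weaker)
    # so that the interictal SOZ group is connected but driven, matching
    # the balanced-to-incoming interictal picture
    W1 <- local_seed(config$seed, {
      cand <- which(diag(n) == 0 & matrix(!soz, n, n, byrow = TRUE) &
                      matrix(!soz, n, n, byrow = FALSE))
      sel <- sample(cand, min(config$n_backbone, length(cand)))
      W1[sel] <- config$backbone_coupling
      aff <- which(matrix(!soz, n, n, byrow = TRUE) &
                     matrix(soz, n, n, byrow = FALSE))
      a <- sample(aff, 1L)
      W1[a] <- config$backbone_coupling
      # zero the reciprocal SOZ -> afferent-source couplings: after the
      # recruitment step they would close a strong feedback cycle with the
      # afferent edge and destabilize the recruitment phase
      j_aff <- (a - 1L) %/% n + 1L
      W1[j_aff, soz] <- 0
      W1
    })
  }
  W2 <- W1
  W2[soz, soz] <- W2[soz, soz] * config$soz_gain; diag(W2) <- 0
  W3 <- W2
  W3[!soz, soz] <- W3[!soz, soz] * config$recruit_gain
  names <- c("interictal", "soz_delta", "recruit")
  raw <- list(W1, W2, W3)
  st <- lapply(seq_along(raw), function(i)
    stabilize_phase(raw[[i]], config$var_order, names[i]))
  mats <- lapply(st, `[[`, "W")
  names(mats) <- names
  for (i in seq_along(mats))
    dimnames(mats[[i]]) <- list(config$channel_labels, config$channel_labels)
  edges <- lapply(mats, function(W) {
    idx <- which(W != 0 & row(W) != col(W), arr.ind = TRUE)
    data.frame(source = config$channel_labels[idx[, "col"]],
               target = config$channel_labels[idx[, "row"]],
               weight = W[idx], stringsAsFactors = FALSE)
  })
  # Transition epochs under the default 120 s span / 10 s window / 1 s step
  # epoching. A sliding-window estimate is attributed to the epoch whose
  # window CENTRE crosses the step time (the standard convention for
  # change localization with symmetric windows); the first epoch containing
  # any post-step sample is reported alongside.
  span <- 120; window <- 10
  boundaries <- c(soz_delta = span - config$t_soz_delta + window / 2,
                  recruit   = span - config$t_recruit + window / 2)
  first_affected <- c(soz_delta = span - config$t_soz_delta + 1,
                      recruit   = span - config$t_recruit + 1)
  structure(
    list(phase_adjacency = mats, planted_edges = edges,
         phase_boundaries = boundaries, first_affected = first_affected,
         rescale = stats::setNames(vapply(st, `[[`, 0, "scale"), names),
         config = config),
    class = "miso_ground_truth")
}

#' 1/f-shaped (pink) noise by spectral shaping of white noise
#'
#' @param n number of samples.
#' @return numeric vector with zero mean and unit variance.
#' @export
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- c(1, seq_len(n - 1))                 # DC bin kept at weight of bin 1
  f <- pmin(f, n - f + 1)                   # fold to two-sided frequencies
  X <- X / sqrt(f)
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  as.numeric(scale(x))
}

var_simulate <- function(Phi_phases, phase_idx, n, fs, p, noise_sd,
                         pink_fraction, burnin_s = 5) {
  nb <- round(burnin_s * fs)
  total <- length(phase_idx) + nb
  phase_idx <- c(rep(phase_idx[1L], nb), phase_idx)
  E <- matrix(stats::rnorm(n * total), n, total)
  if (pink_fraction > 0) {
    P <- t(vapply(seq_len(n), function(i) pink_noise(total), numeric(total)))
    E <- sqrt(1 - pink_fraction) * E + sqrt(pink_fraction) * P
  }
  E <- noise_sd * E
  Y <- matrix(0, n, total)
  Y[, seq_len(p)] <- E[, seq_len(p)]
  for (t in (p + 1L):total) {
    Phi <- Phi_phases[[phase_idx[t]]]
    acc <- E[, t]
    for (l in seq_len(p)) acc <- acc + Phi[[l]] %*% Y[, t - l]
    Y[, t] <- acc
    if (!all(is.finite(Y[, t])) || max(abs(Y[, t])) > 1e6)
      stop("simulated trajectory diverged (unstable process)")
  }
  Y[, (nb + 1L):total, drop = FALSE]
}

#' Simulate a synthetic iEEG recording with planted network ground truth
#'
#' Runs a piecewise-stationary VAR of order `config$var_order` whose coupling
#' matrix switches at the planted step times, driven by Gaussian innovations
#' mixed with pink noise. A 5 s burn-in is generated and discarded. The
#' returned recording spans `[onset - duration, onset)`.
#'
#' @param config a [scenario_config()].
#' @return list with elements `recording` (a [recording()]) and
#'   `ground_truth` (a [build_phase_networks()] result).
#' @export
simulate_recording <- function(config) {
  stopifnot(inherits(config, "miso_scenario"))
  set.seed(config$seed)
  gt <- build_phase_networks(config)
  p <- config$var_order; fs <- config$fs
  Phi_phases <- lapply(gt$phase_adjacency, var_coef_list, p = p)
  T_out <- round(config$duration * fs)
  tau <- (seq_len(T_out)) / fs - config$duration   # time rel. onset, (-D, 0]
  phase_idx <- ifelse(tau < -config$t_soz_delta, 1L,
                      ifelse(tau < -config$t_recruit, 2L, 3L))
  Y <- var_simulate(Phi_phases, phase_idx, config$n_channels, fs, p,
                    config$noise_sd, config$pink_noise_fraction)
  if (config$soz_delta_drive > 0) {
    soz <- config$group_assignment == "SOZ"
    phase <- stats::runif(sum(soz), 0, 2 * pi)
    tt <- 2 * pi * 2 * seq_len(T_out) / fs        # 2 Hz carrier
    osc <- config$soz_delta_drive *
      sin(matrix(tt, sum(soz), T_out, byrow = TRUE) + phase)
    Y[soz, ] <- Y[soz, ] + osc
  }
  rec <- recording(Y, fs = fs, channel_labels = config$channel_labels,
                   groups = config$group_assignment)
  list(recording = rec, ground_truth = gt)
}

#' Simulate a static (single-phase) VAR recording with sparse planted edges
#'
#' A stationary benchmark for estimator edge recovery: `n_edges` distinct
#' directed off-diagonal couplings of strength `coupling` are planted at
#' random, all other cross-couplings are zero.
#'
#' @param n_channels,fs,duration,var_order,noise_sd,pink_noise_fraction as in
#'   [scenario_config()].
#' @param n_edges number of planted directed edges.
#' @param coupling lag-summed gain of each planted edge.
#' @param seed integer seed.
#' @return list with `recording`, `adjacency` (weighted coupling matrix,
#'   entry `(k, j)` = source `j` -> target `k`) and `edges` (data frame).
#' @export
simulate_static_var <- function(n_channels = 8, n_edges = 10, coupling = 0.4,
                                duration = 10, fs = 512, var_order = 3,
                                noise_sd = 1, pink_noise_fraction = 0.05,
                                seed = 1) {
  stopifnot(n_edges <= n_channels * (n_channels - 1))
  set.seed(seed)
  labels <- sprintf("ch%02d", seq_len(n_channels))
  off <- which(diag(n_channels) == 0)
  sel <- sample(off, n_edges)
  W <- matrix(0, n_channels, n_channels)
  W[sel] <- coupling
  st <- stabilize_phase(W, var_order, "static")
  W <- st$W
  dimnames(W) <- list(labels, labels)
  Phi <- list(var_coef_list(W, var_order))
  T_out <- round(duration * fs)
  Y <- var_simulate(Phi, rep(1L, T_out), n_channels, fs, var_order,
                    noise_sd, pink_noise_fraction)
  idx <- which(W != 0, arr.ind = TRUE)
  list(recording = recording(Y, fs = fs, channel_labels = labels),
       adjacency = W,
       edges = data.frame(source = labels[idx[, "col"]],
                          target = labels[idx[, "row"]],
                          weight = W[idx], stringsAsFactors = FALSE),
       rescale = st$scale)
}

#' Write ground-truth edge lists and transition epochs to a directory
#'
#' One tab-separated edge list per phase (`edges_<phase>.tsv` with columns
#' source_label, target_label, weight) plus `transitions.tsv` holding the
#' planted transition epoch indices.
#'
#' @param gt a [build_phase_networks()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(gt, dir) {
  stopifnot(inherits(gt, "miso_ground_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ph in names(gt$planted_edges)) {
    utils::write.table(gt$planted_edges[[ph]],
                       file.path(dir, sprintf("edges_%s.tsv", ph)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  utils::write.table(
    data.frame(transition = names(gt$phase_boundaries),
               epoch_index = as.integer(gt$phase_boundaries)),
    file.path(dir, "transitions.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  invisible(dir)
}
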