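# Shared fixtures and independent oracles, all generated in code.

# Small multichannel recording of white noise.
white_recording <- function(n_channels = 4, seconds = 2, fs = 256, seed = 1) {
  set.seed(seed)
  recording(matrix(rnorm(n_channels * seconds * fs), n_channels),
            fs = fs)
}

sine_recording <- function(freq, seconds = 4, fs = 512, amp = 1) {
  t <- seq_len(seconds * fs) / fs
  recording(rbind(amp * sin(2 * pi * freq * t)), fs = fs,
            channel_labels = "s1")
}

rms <- function(x) sqrt(mean(x^2))

# Random binary directed adjacency in the package's (target, source)
# orientation, zero diagonal.
random_digraph <- function(n, p = 0.3) {
  A <- matrix(rbinom(n * n, 1, p), n, n)
  diag(A) <- 0L
  A
}

as_network <- function(A, groups = NULL) {
  labels <- sprintf("n%02d", seq_len(nrow(A)))
  dimnames(A) <- list(labels, labels)
  if (!is.null(groups)) names(groups) <- labels
  structure(list(adjacency = A, threshold_used = 0, labels = labels,
                 groups = groups, epoch_index = 1L),
            class = "miso_network")
}

as_connectivity <- function(V, mask = rep(FALSE, nrow(V))) {
  labels <- sprintf("n%02d", seq_len(nrow(V)))
  dimnames(V) <- list(labels, labels)
  structure(list(values = V, epoch_index = 1L,
                 rejection_mask = stats::setNames(mask, labels),
                 labels = labels, groups = NULL),
            class = "miso_connectivity")
}

# Exhaustive shortest-path enumeration oracle for directed unweighted
# betweenness: enumerates every shortest s->t path by recursive descent
# over a BFS distance labeling and counts pass-throughs per node.
brute_betweenness <- function(A) {
  # A[k, j] = 1 means edge j -> k
  n <- nrow(A)
  succ <- lapply(seq_len(n), function(j) which(A[, j] == 1))
  bc <- numeric(n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) for (w in succ[[v]])
        if (dist[w] > dist[v] + 1) { dist[w] <- dist[v] + 1; nxt <- c(nxt, w) }
      frontier <- unique(nxt)
    }
    paths_to <- function(t) {
      if (t == s) return(list(s))
      preds <- which(vapply(seq_len(n), function(v)
        A[t, v] == 1 && dist[v] == dist[t] - 1, NA))
      out <- list()
      for (p in preds) for (pp in paths_to(p)) out <- c(out, list(c(pp, t)))
      out
    }
    for (t in seq_len(n)) {
      if (t == s || !is.finite(dist[t])) next
      paths <- paths_to(t)
      if (!length(paths)) next
      inner <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
      if (length(inner))
        for (v in inner) bc[v] <- bc[v] + 1 / length(paths)
    }
  }
  bc
}

# Small three-state scenario (30-epoch span) for fast pipeline tests.
fast_scenario <- function(seed = 1, ...) {
  scenario_config(duration = 45, t_soz_delta = 20, t_recruit = 6,
                  seed = seed, ...)
}
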