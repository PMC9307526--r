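as_igraph <- function(network) {
  stopifnot(inherits(network, "miso_network"))
  # adjacency entry (k, j) encodes edge j -> k, so transpose for igraph's
  # row-source convention
  igraph::graph_from_adjacency_matrix(t(network$adjacency), mode = "directed")
}

#' Degree centrality of a pruned directed network
#'
#' Number of connections at each node: in-degree plus out-degree (the
#' faithful reading of "connections made to each node" for an oriented
#' graph). A single direction can be selected instead.
#'
#' @param network a `"miso_network"`.
#' @param mode `"total"` (default), `"in"`, or `"out"`.
#' @return Named numeric vector of per-node counts.
#' @export
degree_centrality <- function(network, mode = c("total", "in", "out")) {
  mode <- match.arg(mode)
  A <- network$adjacency
  dc <- switch(mode,
               total = rowSums(A) + colSums(A),  # in (row k) + out (col j)
               "in"  = rowSums(A),
               out   = colSums(A))
  stats::setNames(as.numeric(dc), network$labels)
}

#' Betweenness centrality of a pruned directed network
#'
#' Directed, unweighted betweenness: for every ordered pair of distinct
#' nodes, the fraction of shortest paths passing through a node, summed
#' over pairs (raw, unnormalized path counts by default); unreachable pairs
#' contribute nothing.
#'
#' @param network a `"miso_network"`.
#' @param normalized divide by `(n-1)(n-2)`, the number of ordered pairs.
#' @return Named numeric vector of per-node values.
#' @export
betweenness_centrality <- function(network, normalized = FALSE) {
  g <- as_igraph(network)
  bc <- igraph::betweenness(g, directed = TRUE, normalized = normalized)
  stats::setNames(as.numeric(bc), network$labels)
}

#' Per-group mean and standard deviation of a node metric
#'
#' @param values named per-node values (names = channel labels).
#' @param groups named group vector label -> SOZ/PSZ/NSZ.
#' @return Data frame with one row per group: `group`, `mean`, `sd`, `n`.
#' @export
group_summary <- function(values, groups) {
  groups <- validate_groups(groups, names(values))
  out <- lapply(c("SOZ", "PSZ", "NSZ"), function(g) {
    v <- values[names(groups)[groups == g]]
    if (length(v) == 0L) stop("empty group: ", g)
    data.frame(group = g, mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else 0,
               n = length(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

node_edge_counts <- function(network, groups) {
  A <- network$adjacency
  labels <- network$labels
  groups <- validate_groups(groups, labels)
  same <- outer(groups, groups, "==")   # same[i, j]: i and j share a group
  # incident edges of node v: row v (incoming) + column v (outgoing)
  intra_in  <- rowSums(A * same); intra_out <- colSums(A * same)
  tot_in <- rowSums(A); tot_out <- colSums(A)
  data.frame(label = labels, group = unname(groups),
             deg_in = tot_in, deg_out = tot_out,
             intra = intra_in + intra_out,
             total = tot_in + tot_out,
             stringsAsFactors = FALSE)
}

#' Fraction of within-group connections, per group
#'
#' Every edge incident to a node is labeled intragroup (both endpoints in
#' the node's group) or intergroup; the per-node intragroup percentage is
#' then averaged over the nodes of each group. Nodes without any edge carry
#' no proportion and are excluded from the average (their count is
#' reported).
#'
#' @param network a `"miso_network"`.
#' @param groups named group vector; defaults to the network's own.
#' @return Data frame per group: `group`, `mean` and `sd` of the per-node
#'   intragroup percentage, `n_nodes`, `n_zero_degree`.
#' @export
intragroup_fraction <- function(network, groups = network$groups) {
  if (is.null(groups)) stop("no group assignment available")
  counts <- node_edge_counts(network, groups)
  out <- lapply(c("SOZ", "PSZ", "NSZ"), function(g) {
    sub <- counts[counts$group == g, ]
    if (nrow(sub) == 0L) stop("empty group: ", g)
    has <- sub$total > 0
    prop <- 100 * sub$intra[has] / sub$total[has]
    data.frame(group = g,
               mean = if (any(has)) mean(prop) else NA_real_,
               sd = if (sum(has) > 1L) stats::sd(prop) else 0,
               n_nodes = sum(has), n_zero_degree = sum(!has),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Incoming vs outgoing connection percentages, per group
#'
#' For each node with at least one edge, the percentage of its connections
#' that are outgoing (and the complementary incoming percentage, which sums
#' to 100 with it); percentages are averaged over each group's nonzero-
#' degree nodes.
#'
#' @inheritParams intragroup_fraction
#' @return Data frame per group: `group`, `outgoing_mean`, `outgoing_sd`,
#'   `incoming_mean`, `incoming_sd`, `n_nodes`, `n_zero_degree`.
#' @export
inout_fractions <- function(network, groups = network$groups) {
  if (is.null(groups)) stop("no group assignment available")
  counts <- node_edge_counts(network, groups)
  out <- lapply(c("SOZ", "PSZ", "NSZ"), function(g) {
    sub <- counts[counts$group == g, ]
    if (nrow(sub) == 0L) stop("empty group: ", g)
    has <- sub$total > 0
    outp <- 100 * sub$deg_out[has] / sub$total[has]
    data.frame(group = g,
               outgoing_mean = if (any(has)) mean(outp) else NA_real_,
               outgoing_sd = if (sum(has) > 1L) stats::sd(outp) else 0,
               incoming_mean = if (any(has)) mean(100 - outp) else NA_real_,
               incoming_sd = if (sum(has) > 1L) stats::sd(100 - outp) else 0,
               n_nodes = sum(has), n_zero_degree = sum(!has),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Centrality and composition summary for a sequence of networks
#'
#' One row per (epoch, group) with DC/BC mean and SD plus the intragroup
#' and incoming/outgoing percentages -- the tabular record underlying the
#' centrality time-series plots.
#'
#' @param networks list of `"miso_network"` objects.
#' @param groups named group vector; defaults to the first network's.
#' @return Data frame.
#' @export
centrality_timeseries <- function(networks, groups = networks[[1L]]$groups) {
  if (is.null(groups)) stop("no group assignment available")
  rows <- lapply(networks, function(nw) {
    dc <- degree_centrality(nw)
    bc <- betweenness_centrality(nw)
    gs_dc <- group_summary(dc, groups)
    gs_bc <- group_summary(bc, groups)
    intra <- intragroup_fraction(nw, groups)
    io <- inout_fractions(nw, groups)
    data.frame(epoch_index = nw$epoch_index,
               group = gs_dc$group,
               dc_mean = gs_dc$mean, dc_sd = gs_dc$sd,
               bc_mean = gs_bc$mean, bc_sd = gs_bc$sd,
               intragroup_pct = intra$mean,
               outgoing_pct = io$outgoing_mean,
               incoming_pct = io$incoming_mean,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
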