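#' Assemble a per-epoch connectivity matrix from MISO models
#'
#' Entry `(k, j)` of the result is `input_gain(model_k, j)`, the Euclidean
#' norm of the column of `B_k` belonging to input `j`: the directed
#' influence of source channel `j` on target channel `k`. The matrix is
#' non-symmetric with a zero diagonal. Targets whose model failed residual
#' validation contribute an all-zero row and a set bit in the rejection
#' mask.
#'
#' @param models named list of `"miso_model"` objects, one per channel (as
#'   from [fit_miso_epoch()]).
#' @param epoch_index epoch index to stamp on the result.
#' @param apply_rejections zero out rows of rejected models (default `TRUE`;
#'   models without diagnostics are kept).
#' @param groups optional named group vector (label -> SOZ/PSZ/NSZ) carried
#'   through to downstream metrics.
#' @return Object of class `"miso_connectivity"`: `values` (N x N matrix),
#'   `epoch_index`, `rejection_mask` (named logical), `labels`, `groups`.
#' @export
assemble_connectivity <- function(models, epoch_index = NA_integer_,
                                  apply_rejections = TRUE, groups = NULL) {
  targets <- vapply(models, `[[`, "", "target_channel")
  if (anyDuplicated(targets)) stop("duplicate target channels in model set")
  labels <- targets
  N <- length(labels)
  vals <- matrix(0, N, N, dimnames = list(labels, labels))
  mask <- stats::setNames(rep(FALSE, N), labels)
  for (mod in models) {
    k <- mod$target_channel
    rejected <- apply_rejections && !is.null(mod$diagnostics) &&
      !isTRUE(mod$diagnostics$accepted)
    if (rejected) { mask[k] <- TRUE; next }
    vals[k, mod$input_channels] <- sqrt(colSums(mod$B^2))
  }
  if (!is.null(groups)) groups <- validate_groups(groups, labels)
  structure(
    list(values = vals, epoch_index = epoch_index, rejection_mask = mask,
         labels = labels, groups = groups),
    class = "miso_connectivity")
}

#' @export
print.miso_connectivity <- function(x, ...) {
  cat(sprintf("<miso_connectivity> epoch %s, %d channels, %d rejected rows\n",
              as.character(x$epoch_index), length(x$labels),
              sum(x$rejection_mask)))
  invisible(x)
}

# Off-diagonal entries of non-rejected rows, pooled across matrices.
pool_entries <- function(matrices) {
  if (inherits(matrices, "miso_connectivity")) matrices <- list(matrices)
  unlist(lapply(matrices, function(cm) {
    keep <- !cm$rejection_mask
    v <- cm$values[keep, , drop = FALSE]
    offdiag <- col(cm$values)[keep, , drop = FALSE] !=
      row(cm$values)[keep, , drop = FALSE]
    v[offdiag]
  }), use.names = FALSE)
}

#' Pooled percentile threshold over connectivity matrices
#'
#' Computes the stated percentile (linear-interpolation definition,
#' `quantile(type = 7)`) of all off-diagonal influence values pooled across
#' the supplied matrices; rows under a rejection mask are excluded so that
#' rejected models do not deflate the threshold.
#'
#' @param matrices a `"miso_connectivity"` or list of them.
#' @param percentile percentile in `(0, 100)`.
#' @return The threshold (dimensionless scalar).
#' @export
pooled_threshold <- function(matrices, percentile = 95) {
  pool <- pool_entries(matrices)
  if (length(pool) == 0L) stop("empty pool: no unmasked off-diagonal entries")
  unname(stats::quantile(pool, percentile / 100, type = 7))
}

#' Prune a connectivity matrix to a binary directed graph
#'
#' Retains edge `j -> k` iff `values[k, j] > threshold` (strictly above);
#' everything else is set to zero. Downstream graph metrics treat the result
#' as an unweighted directed graph, since relative strength among retained
#' (strong) connections is deliberately not assessed.
#'
#' @param matrix a `"miso_connectivity"`.
#' @param threshold pruning threshold, `>= 0` typically from
#'   [pooled_threshold()].
#' @return Object of class `"miso_network"`: binary `adjacency` (entry
#'   `(k, j)` = 1 for edge `j -> k`), `threshold_used`, `labels`, `groups`,
#'   `epoch_index`.
#' @export
prune <- function(matrix, threshold) {
  stopifnot(inherits(matrix, "miso_connectivity"))
  adj <- (matrix$values > threshold) * 1L
  diag(adj) <- 0L
  structure(
    list(adjacency = adj, threshold_used = threshold,
         labels = matrix$labels, groups = matrix$groups,
         epoch_index = matrix$epoch_index),
    class = "miso_network")
}

#' Keep only the strongest fraction of connections
#'
#' Retains the `ceiling(fraction * pool size)` largest off-diagonal entries
#' (the reduced "top 1%" visualization network). Ties are broken
#' deterministically by (row, column) index order; the number of tied
#' entries at the cut is recorded in attribute `"ties_at_cut"`.
#'
#' @param matrix a `"miso_connectivity"`.
#' @param fraction fraction of the off-diagonal pool to keep, in `(0, 1]`.
#' @return A `"miso_network"`.
#' @export
top_fraction_network <- function(matrix, fraction = 0.01) {
  stopifnot(inherits(matrix, "miso_connectivity"),
            fraction > 0, fraction <= 1)
  N <- nrow(matrix$values)
  off <- which(row(matrix$values) != col(matrix$values))
  k <- ceiling(fraction * length(off))
  ord <- off[order(-matrix$values[off], (off - 1L) %% N + 1L,
                   (off - 1L) %/% N + 1L)]
  keep <- ord[seq_len(k)]
  cutval <- matrix$values[keep[k]]
  ties <- sum(matrix$values[off] == cutval) - sum(matrix$values[keep] == cutval)
  adj <- matrix(0L, N, N, dimnames = dimnames(matrix$values))
  adj[keep] <- 1L
  out <- structure(
    list(adjacency = adj, threshold_used = cutval,
         labels = matrix$labels, groups = matrix$groups,
         epoch_index = matrix$epoch_index),
    class = "miso_network")
  attr(out, "ties_at_cut") <- ties
  out
}

#' @export
print.miso_network <- function(x, ...) {
  cat(sprintf("<miso_network> epoch %s, %d nodes, %d edges (threshold %.4g)\n",
              as.character(x$epoch_index), length(x$labels),
              sum(x$adjacency), x$threshold_used))
  invisible(x)
}

#' Edge list of a pruned network or connectivity matrix
#'
#' @param x a `"miso_network"` or `"miso_connectivity"`.
#' @return Data frame with columns `source`, `target`, `weight`,
#'   `epoch_index` (weight is 1 for binary networks).
#' @export
edge_list <- function(x) {
  vals <- if (inherits(x, "miso_network")) x$adjacency else x$values
  idx <- which(vals != 0 & row(vals) != col(vals), arr.ind = TRUE)
  data.frame(source = x$labels[idx[, "col"]],
             target = x$labels[idx[, "row"]],
             weight = vals[idx],
             epoch_index = rep(x$epoch_index, nrow(idx)),
             stringsAsFactors = FALSE)
}

#' Write edge lists for a set of networks
#'
#' Tab-separated columns: source_label, target_label, weight, epoch_index.
#'
#' @param networks list of `"miso_network"` (or connectivity) objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edge_lists <- function(networks, path) {
  if (!is.list(networks) || inherits(networks, c("miso_network",
                                                 "miso_connectivity")))
    networks <- list(networks)
  tab <- do.call(rbind, lapply(networks, edge_list))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
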