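#' Kruskal-Wallis omnibus test across groups
#'
#' Rank-based H statistic with tie correction and a chi-square p-value on
#' k - 1 degrees of freedom (delegates to [stats::kruskal.test()]). When
#' every value across all groups is identical the statistic is defined as
#' H = 0, p = 1.
#'
#' @param samples list of numeric vectors, one per group (>= 2 nonempty
#'   groups, total n >= 5).
#' @return List with `statistic` (H), `p_value`, `df`.
#' @export
kruskal_wallis <- function(samples) {
  stopifnot(is.list(samples), length(samples) >= 2L)
  if (any(vapply(samples, length, 0L) == 0L)) stop("empty group")
  if (sum(lengths(samples)) < 5L) stop("too few observations (need >= 5)")
  x <- unlist(samples, use.names = FALSE)
  if (length(unique(x)) == 1L)
    return(list(statistic = 0, p_value = 1, df = length(samples) - 1L))
  g <- factor(rep(seq_along(samples), lengths(samples)))
  kt <- stats::kruskal.test(x, g)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}

#' Dunn's post-hoc pairwise comparisons on mean ranks
#'
#' Pairwise z statistics on joint-ranking mean ranks with the standard Dunn
#' variance and tie correction:
#' \deqn{z_{ij} = (\bar R_i - \bar R_j) / \sqrt{\left(\frac{n(n+1)}{12} -
#'   \frac{\sum_t (t^3 - t)}{12(n-1)}\right)\left(\frac{1}{n_i} +
#'   \frac{1}{n_j}\right)}}
#' Two-sided p-values are corrected for multiplicity over the pairwise
#' family (Holm by default).
#'
#' @param samples list of numeric vectors, one per group (named if
#'   possible).
#' @param correction `"holm"` (default), `"bonferroni"`, or `"none"`.
#' @return List with `p` (symmetric matrix of corrected p-values, unit
#'   diagonal), `z` (signed pairwise z matrix), `mean_ranks`, and the
#'   correction used.
#' @export
dunn_posthoc <- function(samples, correction = c("holm", "bonferroni", "none")) {
  correction <- match.arg(correction)
  stopifnot(is.list(samples), length(samples) >= 2L)
  k <- length(samples)
  nm <- names(samples)
  if (is.null(nm)) nm <- paste0("group", seq_len(k))
  x <- unlist(samples, use.names = FALSE)
  g <- rep(seq_len(k), lengths(samples))
  n <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ni <- lengths(samples)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  base_var <- n * (n + 1) / 12 - tie_term
  z <- matrix(0, k, k, dimnames = list(nm, nm))
  praw <- matrix(1, k, k, dimnames = list(nm, nm))
  pairs <- utils::combn(k, 2)
  pvec <- numeric(ncol(pairs))
  for (c_ in seq_len(ncol(pairs))) {
    i <- pairs[1L, c_]; j <- pairs[2L, c_]
    se <- sqrt(base_var * (1 / ni[i] + 1 / ni[j]))
    # se = 0 only when every observation is tied across all groups
    zij <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
    z[i, j] <- zij; z[j, i] <- -zij
    pvec[c_] <- 2 * stats::pnorm(-abs(zij))
  }
  padj <- switch(correction,
                 holm = holm_adjust(pvec),
                 bonferroni = pmin(1, pvec * length(pvec)),
                 none = pvec)
  for (c_ in seq_len(ncol(pairs))) {
    i <- pairs[1L, c_]; j <- pairs[2L, c_]
    praw[i, j] <- praw[j, i] <- padj[c_]
  }
  diag(praw) <- 1
  list(p = praw, z = z, mean_ranks = stats::setNames(as.numeric(rbar), nm),
       correction = correction)
}

#' Group/state statistics report
#'
#' Runs the Kruskal-Wallis omnibus and Dunn post hoc for a metric across
#' the three channel groups within each network state.
#'
#' @param values data frame with columns `group`, `state`, `value`.
#' @param correction multiplicity correction for [dunn_posthoc()].
#' @return Data frame keyed by (state, comparison) with the omnibus H/p and
#'   the pairwise corrected p.
#' @export
group_state_report <- function(values, correction = "holm") {
  stopifnot(all(c("group", "state", "value") %in% names(values)))
  out <- list()
  for (st in unique(values$state)) {
    sub <- values[values$state == st, ]
    groups <- split(sub$value, sub$group)
    groups <- groups[lengths(groups) > 0L]
    if (length(groups) < 2L) next
    kw <- kruskal_wallis(groups)
    dn <- dunn_posthoc(groups, correction = correction)
    prs <- utils::combn(names(groups), 2)
    for (c_ in seq_len(ncol(prs))) {
      out[[length(out) + 1L]] <- data.frame(
        state = st, comparison = paste(prs[1L, c_], prs[2L, c_], sep = " vs "),
        H = kw$statistic, omnibus_p = kw$p_value,
        pairwise_p = dn$p[prs[1L, c_], prs[2L, c_]],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
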