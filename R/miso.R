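# Lagged regression design shared by every target channel of an epoch.
# For data rows t = (m+1)..T the response block holds Y(t) for all N
# channels and the design block holds [Y(t-1), ..., Y(t-m)]; the coefficient
# for lag l of channel j sits at row (l-1)*N + j. Because the regressor set
# (m lags of every channel) is identical for all targets, one QR
# factorization serves all N MISO fits of an epoch.
miso_design <- function(Yt, m) {
  N <- ncol(Yt)
  E <- stats::embed(Yt, m + 1L)
  list(resp = E[, seq_len(N), drop = FALSE],
       X = E[, -seq_len(N), drop = FALSE])
}

miso_fit_core <- function(epoch, m, train_fraction = 0.8) {
  Yt <- t(epoch$samples)
  if (!all(is.finite(Yt))) stop("epoch contains non-finite samples")
  Tn <- nrow(Yt); N <- ncol(Yt)
  n_train <- floor(train_fraction * Tn)
  n_par <- N * m
  if (n_train - m <= 10 * n_par)
    stop(sprintf("epoch too short: %d training samples for %d parameters",
                 n_train - m, n_par))
  d <- miso_design(Yt[seq_len(n_train), , drop = FALSE], m)
  qrX <- qr(d$X)
  if (qrX$rank == ncol(d$X)) {
    coef <- qr.coef(qrX, d$resp)          # (N*m) x N, one column per target
  } else if (ncol(d$X) - qrX$rank <= m) {
    # Structural collinearity: after common average referencing the channels
    # sum to zero at every sample, so the m lag-sum columns are exactly
    # dependent and the least-squares solution is non-unique. The
    # minimum-norm solution (truncated SVD) is the unique completion that
    # treats all channels symmetrically, so input-gain comparisons stay
    # unbiased. Deficiency beyond m indicates degenerate data and is an
    # error.
    sv <- svd(d$X)
    keep <- sv$d > max(dim(d$X)) * .Machine$double.eps * sv$d[1L]
    coef <- sv$v[, keep, drop = FALSE] %*%
      ((crossprod(sv$u[, keep, drop = FALSE], d$resp)) / sv$d[keep])
  } else {
    stop(sprintf("rank-deficient regression in epoch %s (rank %d < %d)",
                 as.character(epoch$index), qrX$rank, ncol(d$X)))
  }
  fitted <- d$X %*% coef
  res_train <- d$resp - fitted
  list(coef = coef, n_train = n_train, n_obs = nrow(d$X),
       mse_train = colMeans(res_train^2), fitted = fitted,
       Yt = Yt, N = N, m = m, labels = epoch$channel_labels,
       train_fraction = train_fraction)
}

# Observer canonical state-space realization of the ARX predictor of target
# k: A is the m x m companion of the self-lag coefficients, column j of B
# holds the m lag coefficients of input j, C reads the first state.
miso_realize <- function(core, k) {
  m <- core$m; N <- core$N
  ck <- core$coef[, k]
  a <- ck[(seq_len(m) - 1L) * N + k]
  inputs <- setdiff(seq_len(N), k)
  B <- vapply(inputs, function(j) ck[(seq_len(m) - 1L) * N + j],
              numeric(m))
  B <- matrix(B, nrow = m)
  A <- if (m == 1L) matrix(a, 1L, 1L) else
    unname(cbind(a, rbind(diag(1, m - 1L, m - 1L), 0)))
  C <- matrix(c(1, rep(0, m - 1L)), 1L, m)
  colnames(B) <- core$labels[inputs]
  structure(
    list(target_channel = core$labels[k],
         input_channels = core$labels[inputs],
         A = A, B = B, C = C, m = m,
         a = a,
         train_fraction = core$train_fraction,
         n_train_obs = core$n_obs,
         mse_train = unname(core$mse_train[k]),
         epoch_index = NA_integer_,
         diagnostics = NULL),
    class = "miso_model")
}

#' Fit a MISO state-space model for one target channel of an epoch
#'
#' Each channel is treated as the output of a linear time-invariant
#' multi-input single-output system driven by all other channels. The model
#' is estimated as a multi-input ARX predictor of order `m` -- `m` lags of
#' the target and of every input channel -- by QR-factorized least squares
#' on the first `train_fraction` (80%) of the epoch, then realized in
#' observer canonical state-space form `(A, B, C)` so that the Euclidean
#' norms of the columns of `B` quantify each input's influence.
#'
#' @param epoch an epoch from [epoch_sliding()].
#' @param k target channel label (or index).
#' @param m state dimension (ARX order), `>= 1`.
#' @param train_fraction fraction of the epoch used for estimation.
#' @return An object of class `"miso_model"` with fields `A` (`m x m`),
#'   `B` (`m x (N-1)`, one column per input), `C` (`1 x m`), the self-lag
#'   coefficients `a`, training diagnostics, and labels.
#' @export
fit_miso <- function(epoch, k, m, train_fraction = 0.8) {
  stopifnot(m >= 1)
  core <- miso_fit_core(epoch, m, train_fraction)
  ki <- if (is.character(k)) match(k, core$labels) else as.integer(k)
  if (is.na(ki) || ki < 1L || ki > core$N) stop("unknown target channel: ", k)
  mod <- miso_realize(core, ki)
  mod$epoch_index <- epoch$index
  mod
}

#' Fit MISO models for every channel of an epoch
#'
#' Shares one QR factorization across all targets (the regressor set is the
#' same), then optionally validates each model on the held-out tail of the
#' epoch.
#'
#' @param epoch an epoch from [epoch_sliding()].
#' @param m state dimension.
#' @param validate if `TRUE`, attach a [validate_model()] report to each
#'   model's `diagnostics`.
#' @param train_fraction fraction of the epoch used for estimation.
#' @return Named list of `"miso_model"` objects, one per channel.
#' @export
fit_miso_epoch <- function(epoch, m, validate = TRUE, train_fraction = 0.8) {
  core <- miso_fit_core(epoch, m, train_fraction)
  test <- miso_test_residuals(core)
  reports <- if (validate) epoch_residual_tests(test$res, test$U) else NULL
  models <- lapply(seq_len(core$N), function(k) {
    mod <- miso_realize(core, k)
    mod$epoch_index <- epoch$index
    if (validate) mod$diagnostics <- reports[[k]]
    mod$mse_test <- mean(test$res[, k]^2)
    mod
  })
  stats::setNames(models, core$labels)
}

# Held-out one-step-ahead residuals for all targets: responses are the final
# (1 - train_fraction) of the epoch, never used in fitting; lagged
# regressors may reach back into the training tail.
miso_test_residuals <- function(core) {
  Tn <- nrow(core$Yt)
  idx <- (core$n_train + 1L):Tn
  d <- miso_design(core$Yt[(core$n_train - core$m + 1L):Tn, , drop = FALSE],
                   core$m)
  res <- d$resp - d$X %*% core$coef
  list(res = res, U = core$Yt[idx, , drop = FALSE], test_idx = idx)
}

#' @export
print.miso_model <- function(x, ...) {
  cat(sprintf("<miso_model> target %s, m = %d, %d inputs\n",
              x$target_channel, x$m, ncol(x$B)))
  if (!is.null(x$diagnostics))
    cat(sprintf("  validation: whiteness_p = %.3f, independence_p = %.3f, %s\n",
                x$diagnostics$whiteness_p, x$diagnostics$independence_p,
                if (x$diagnostics$accepted) "accepted" else "rejected"))
  invisible(x)
}

#' Whiteness and independence tests on held-out residuals
#'
#' Whiteness is assessed by a Ljung-Box portmanteau statistic over `lags`
#' lags. Independence is assessed by the maximum absolute cross-correlation
#' between the residuals and *past* input samples (lags `1..lags` for every
#' input), referred to its Gaussian null and Sidak-corrected for the number
#' of lag-by-input comparisons; correlation with past inputs signals
#' unmodeled input influence. The causal direction is tested by default
#' because iEEG channels form a feedback system (every channel drives every
#' other, and common average referencing mixes them instantaneously), so
#' correlation at zero and negative lags is expected even for a correct
#' model; `two_sided = TRUE` tests lags `-lags..lags` instead. The two
#' p-values are Holm-adjusted as a family so that the joint validation
#' decision -- accept only if both adjusted p-values are at least `alpha`
#' -- has size `alpha` under the null of white, input-independent
#' residuals.
#'
#' @param residuals numeric vector of held-out one-step prediction errors.
#' @param inputs matrix of input-channel samples over the same span (one
#'   column per input), or `NULL` to skip the independence test.
#' @param lags number of lags for both tests.
#' @param alpha acceptance level.
#' @param two_sided test residual-input correlation in both lag directions.
#' @return List with `whiteness_p`, `independence_p` (family-adjusted),
#'   `accepted`, `degenerate`, `mse` and the raw unadjusted p-values.
#' @export
residual_tests <- function(residuals, inputs = NULL, lags = 20, alpha = 0.05,
                           two_sided = FALSE) {
  n <- length(residuals)
  if (n < 2L * lags) stop("test segment shorter than 2*lags samples")
  if (stats::sd(residuals) < 1e-14) {   # variance-zero guard (degenerate fit)
    return(list(whiteness_p = 0, independence_p = 0, accepted = FALSE,
                degenerate = TRUE, mse = mean(residuals^2),
                whiteness_p_raw = 0, independence_p_raw = 0))
  }
  p_white <- stats::Box.test(residuals, lag = lags, type = "Ljung-Box")$p.value
  p_indep <- NA_real_
  if (!is.null(inputs) && ncol(inputs) > 0L) {
    r <- as.numeric(scale(residuals))
    U <- scale(inputs)
    nol <- n - lags
    # causal direction, r(t) vs u(t - l): lag block l of embed(U) holds
    # u(t - l); one cross-product covers all (input, lag) pairs on the
    # common overlap. Lag 0 is excluded (no feedthrough in the model).
    Ul <- stats::embed(U, lags + 1L)            # rows t = lags+1 .. n
    ra <- r[(lags + 1L):n]
    cc_causal <- crossprod(Ul[, -seq_len(ncol(U)), drop = FALSE], ra) / nol
    zmax <- max(abs(cc_causal))
    if (two_sided) {
      # feedback direction (+ lag 0): u(t) vs r(t - l), l = 0..lags
      Rl <- stats::embed(r, lags + 1L)
      Ua <- U[(lags + 1L):n, , drop = FALSE]
      cc_bwd <- crossprod(Ua, Rl) / nol
      zmax <- max(zmax, max(abs(cc_bwd)))
    }
    K <- (if (two_sided) 2L * lags + 1L else lags) * ncol(inputs)
    zmax <- zmax * sqrt(nol)
    p_each <- 2 * stats::pnorm(-zmax)
    p_indep <- 1 - (1 - min(1, p_each))^K
  }
  raw <- c(whiteness = p_white, independence = p_indep)
  present <- !is.na(raw)
  adj <- raw
  adj[present] <- holm_adjust(raw[present])
  accepted <- all(adj[present] >= alpha)
  list(whiteness_p = unname(adj["whiteness"]),
       independence_p = unname(adj["independence"]),
       accepted = accepted, degenerate = FALSE,
       mse = mean(residuals^2),
       whiteness_p_raw = unname(raw["whiteness"]),
       independence_p_raw = unname(raw["independence"]))
}

# Validation for all targets of an epoch in one pass: the input embedding
# and the residual-input cross-products are shared across targets (one
# matrix product), which matters when validating thousands of epoch fits.
# Per-target results are identical to residual_tests() on that target's
# residuals and inputs.
epoch_residual_tests <- function(res, U, lags = 20, alpha = 0.05) {
  n <- nrow(res); N <- ncol(res)
  stopifnot(ncol(U) == N, nrow(U) == n)
  if (n < 2L * lags) stop("test segment shorter than 2*lags samples")
  sds <- apply(res, 2L, stats::sd)
  Us <- scale(U); Us[!is.finite(Us)] <- 0
  Rs <- scale(res); Rs[!is.finite(Rs)] <- 0
  Ul <- stats::embed(Us, lags + 1L)
  nol <- n - lags
  CC <- crossprod(Ul, Rs[(lags + 1L):n, , drop = FALSE]) / nol
  lapply(seq_len(N), function(k) {
    if (sds[k] < 1e-14)
      return(list(whiteness_p = 0, independence_p = 0, accepted = FALSE,
                  degenerate = TRUE, mse = mean(res[, k]^2),
                  whiteness_p_raw = 0, independence_p_raw = 0))
    rows <- as.vector(outer(setdiff(seq_len(N), k), seq_len(lags) * N, "+"))
    zmax <- max(abs(CC[rows, k])) * sqrt(nol)
    p_white <- stats::Box.test(res[, k], lag = lags,
                               type = "Ljung-Box")$p.value
    p_indep <- 1 - (1 - min(1, 2 * stats::pnorm(-zmax)))^(lags * (N - 1L))
    raw <- c(whiteness = p_white, independence = p_indep)
    adj <- holm_adjust(raw)
    list(whiteness_p = adj[1L], independence_p = adj[2L],
         accepted = all(adj >= alpha), degenerate = FALSE,
         mse = mean(res[, k]^2),
         whiteness_p_raw = p_white, independence_p_raw = p_indep)
  })
}

holm_adjust <- function(p) {
  k <- length(p)
  o <- order(p)
  adj <- pmin(1, (k - seq_len(k) + 1L) * p[o])
  adj <- cummax(adj)
  out <- numeric(k)
  out[o] <- adj
  out
}

#' Validate a fitted MISO model on the held-out tail of its epoch
#'
#' Computes one-step-ahead residuals on the final `1 - train_fraction`
#' (20%) of the epoch -- samples never used for estimation -- and applies
#' [residual_tests()]. A model is accepted only if both the whiteness and
#' the input-independence test pass at the 95% level.
#'
#' @param model a [fit_miso()] model.
#' @param epoch the epoch the model was fitted on.
#' @param lags test lags.
#' @return A validation report, see [residual_tests()]; also contains
#'   `n_test` and the residual vector.
#' @export
validate_model <- function(model, epoch, lags = 20) {
  stopifnot(inherits(model, "miso_model"))
  core <- miso_fit_core(epoch, model$m, model$train_fraction)
  k <- match(model$target_channel, core$labels)
  if (is.na(k)) stop("model target not present in epoch")
  test <- miso_test_residuals(core)
  rep <- residual_tests(test$res[, k], test$U[, -k, drop = FALSE], lags = lags)
  rep$residuals <- test$res[, k]
  rep$n_test <- length(rep$residuals)
  rep
}

#' Akaike Information Criterion for a least-squares fit
#'
#' `n_obs * log(mse) + 2 * n_params` (natural logarithm).
#'
#' @param n_obs number of observations.
#' @param mse mean squared error of the fit.
#' @param n_params number of estimated parameters.
#' @return AIC value (dimensionless).
#' @export
aic <- function(n_obs, mse, n_params) {
  stopifnot(n_obs > 0, n_params >= 0)
  if (!is.finite(mse) || mse <= 0) stop("degenerate fit: mse must be > 0")
  n_obs * log(mse) + 2 * n_params
}

#' Select a shared state dimension by average AIC
#'
#' Fits every channel of every supplied epoch at each candidate order,
#' averages the training AIC across channels and epochs, and returns the
#' minimizing order (ties broken toward the smaller order), so that models
#' of identical size can be used for every contact and epoch. Candidate
#' orders at which every single fit fails validation are excluded.
#'
#' @param epochs list of epochs (typically a subsample, e.g. every 10th).
#' @param m_grid candidate state dimensions.
#' @param validate whether to run residual validation (used only to exclude
#'   orders rejected for every fit).
#' @return The selected order `m*` (integer), with the per-order average AIC
#'   table in attribute `"aic_table"`.
#' @export
select_order <- function(epochs, m_grid = 1:8, validate = TRUE) {
  stopifnot(length(m_grid) >= 1)
  if (inherits(epochs, "miso_epoch")) epochs <- list(epochs)
  m_grid <- sort(unique(as.integer(m_grid)))
  avg <- rep(NA_real_, length(m_grid))
  for (i in seq_along(m_grid)) {
    m <- m_grid[i]
    aics <- c(); any_ok <- FALSE
    for (ep in epochs) {
      core <- miso_fit_core(ep, m)
      n_par <- core$N * m
      aics <- c(aics, vapply(core$mse_train, function(s)
        aic(core$n_obs, s, n_par), 0))
      if (validate) {
        test <- miso_test_residuals(core)
        ok <- vapply(seq_len(core$N), function(k)
          residual_tests(test$res[, k], test$U[, -k, drop = FALSE])$accepted,
          NA)
        any_ok <- any_ok || any(ok)
      } else any_ok <- TRUE
    }
    if (any_ok) avg[i] <- mean(aics)
  }
  if (all(is.na(avg))) stop("every candidate order was rejected")
  m_star <- m_grid[which.min(avg)]   # which.min takes the first (smallest) tie
  attr(m_star, "aic_table") <- data.frame(m = m_grid, mean_aic = avg)
  m_star
}

#' Influence gain of one input on a MISO model's target
#'
#' The Euclidean norm of the corresponding column of the input matrix `B`,
#' the model-based measure of directed influence of channel `j` on the
#' model's target channel.
#'
#' @param model a [fit_miso()] model.
#' @param j input channel label.
#' @return Non-negative scalar.
#' @export
input_gain <- function(model, j) {
  stopifnot(inherits(model, "miso_model"))
  if (!j %in% model$input_channels) stop("unknown input channel: ", j)
  sqrt(sum(model$B[, j]^2))
}
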