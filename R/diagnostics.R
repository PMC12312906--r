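# MCMC convergence diagnostics: split R-hat and rank-normalized split R-hat.
# Split R-hat compares between- and within-chain variance after splitting
# each chain in half; rank normalization (ranks mapped through the normal
# quantile function) makes the diagnostic robust to heavy tails.

# Internal: split each column (chain) of a draws matrix into halves.
split_chains <- function(mat) {
  n <- nrow(mat)
  half <- n %/% 2
  cbind(mat[seq_len(half), , drop = FALSE],
        mat[(n - half + 1):n, , drop = FALSE])
}

# Internal: basic (potential scale reduction) R-hat on a draws-by-chains
# matrix; returns NaN for zero within-chain variance.
rhat_basic <- function(mat) {
  n <- nrow(mat)
  if (n < 2) return(NaN)
  w <- mean(apply(mat, 2, var))
  b <- n * var(colMeans(mat))
  if (!is.finite(w) || w == 0) return(NaN)
  sqrt(((n - 1) / n * w + b / n) / w)
}

# Internal: rank-normalize draws jointly across chains.
rank_normalize <- function(mat) {
  s <- length(mat)
  z <- qnorm((rank(mat, ties.method = "average") - 3 / 8) / (s + 1 / 4))
  matrix(z, nrow = nrow(mat), ncol = ncol(mat))
}

#' Split R-hat of a draws-by-chains matrix
#'
#' @param mat Numeric matrix, iterations in rows, chains in columns.
#' @param rank_normalized Rank-normalize before computing R-hat?
#' @return Scalar R-hat (NaN when the parameter is constant).
#' @export
rhat <- function(mat, rank_normalized = FALSE) {
  stopifnot(is.matrix(mat))
  if (ncol(mat) < 2) stop("R-hat requires at least 2 chains")
  sp <- split_chains(mat)
  if (rank_normalized) sp <- rank_normalize(sp)
  rhat_basic(sp)
}

#' Convergence diagnostics for a fit
#'
#' Computes split R-hat and rank-normalized split R-hat for every sampled
#' parameter. The convergence flag requires split R-hat < 1.05 (the
#' conventional gate) for all non-degenerate parameters; parameters that are
#' constant across all draws (e.g. structurally fixed ones) are reported as
#' `NA` with a warning.
#'
#' @param fit A `loco_fit` (or a 3-d array draw x chain x parameter).
#' @param threshold Convergence gate on split R-hat, default 1.05.
#' @return `data.frame` with `parameter`, `rhat`, `rank_rhat`, `converged`;
#'   attribute `converged` gives the overall flag.
#' @export
diagnose <- function(fit, threshold = 1.05) {
  draws <- if (inherits(fit, "loco_fit")) fit$draws else fit
  stopifnot(length(dim(draws)) == 3)
  if (dim(draws)[2] < 2) stop("diagnose requires at least 2 chains")
  pars <- dimnames(draws)[[3]] %||% paste0("par", seq_len(dim(draws)[3]))
  r <- rr <- rep(NA_real_, length(pars))
  degenerate <- character(0)
  for (j in seq_along(pars)) {
    mat <- draws[, , j, drop = TRUE]
    if (!is.matrix(mat)) mat <- matrix(mat, ncol = dim(draws)[2])
    if (var(as.vector(mat)) == 0) {
      degenerate <- c(degenerate, pars[j])
      next
    }
    r[j] <- rhat(mat)
    rr[j] <- rhat(mat, rank_normalized = TRUE)
  }
  if (length(degenerate))
    warning("R-hat undefined for constant parameter(s): ",
            paste(degenerate, collapse = ", "))
  out <- data.frame(parameter = pars, rhat = r, rank_rhat = rr,
                    converged = is.na(r) | r < threshold,
                    stringsAsFactors = FALSE)
  attr(out, "converged") <- all(r[!is.na(r)] < threshold)
  out
}

#' WAIC from a fitted model
#'
#' Watanabe-Akaike information criterion, `-2 * (lppd - p_waic)`, with the
#' variance-based penalty `p_waic = sum_i var_s(log p(y_i | theta_s))`.
#' The pointwise log-likelihood is recomputed from the retained draws by
#' rerunning the forward model, so no pointwise storage is needed during
#' sampling.
#'
#' @param fit A `loco_fit`.
#' @return List with `waic`, `lppd`, `p_waic`, `n_obs`.
#' @export
loco_waic <- function(fit) {
  stopifnot(inherits(fit, "loco_fit"))
  ll <- pointwise_loglik(fit)
  s <- nrow(ll)
  # lppd_i = log mean_s exp(ll_si), computed stably
  mx <- apply(ll, 2, max)
  lppd <- sum(mx + log(colMeans(exp(sweep(ll, 2, mx)))))
  p_waic <- sum(apply(ll, 2, var))
  list(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic,
       n_obs = ncol(ll))
}

# Internal: draws x observation matrix of log-likelihoods.
pointwise_loglik <- function(fit) {
  m <- posterior_matrix(fit)
  ids <- fit$participants$participant_id
  cols <- function(stub) match(paste0(stub, "[", ids, "]"), colnames(m)) - 1L
  col_map <- cbind(cols("B"), cols("q"), cols("tau"),
                   cols("x1_low"), cols("x1_high"))
  nu_col <- match("nu", colnames(m)) - 1L
  pointwise_loglik_cpp(fit$data, m, col_map, nu_col,
                       fit$variant == "select")
}

#' Compare fitted models by WAIC
#'
#' All fits must be estimated on identical data (checked by hash). Lower
#' WAIC is better; the table is sorted best-first.
#'
#' @param fits Named list of `loco_fit` objects.
#' @return `data.frame` with `model`, `waic`, `lppd`, `p_waic`,
#'   `delta_waic`, sorted by WAIC.
#' @export
loco_compare <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 2)
  hashes <- vapply(fits, function(f) f$data_hash, character(1))
  if (length(unique(hashes)) != 1)
    stop("fits were not estimated on identical data")
  nm <- names(fits) %||% vapply(fits, function(f) f$model, character(1))
  w <- lapply(fits, loco_waic)
  out <- data.frame(model = nm,
                    waic = vapply(w, `[[`, numeric(1), "waic"),
                    lppd = vapply(w, `[[`, numeric(1), "lppd"),
                    p_waic = vapply(w, `[[`, numeric(1), "p_waic"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$waic), , drop = FALSE]
  out$delta_waic <- out$waic - out$waic[1]
  rownames(out) <- NULL
  out
}
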