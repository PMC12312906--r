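# Hierarchical Bayesian estimation of the dual-context state-space model.
#
# Three levels: Student-t observations around the model's output (level 1);
# per-participant learning rate B_p and interference q_p as
# sigmoid(Normal(theta_g, sigma_g)), observation scale tau_p (half-normal),
# baseline scaling k_p (truncated normal) and free initial states x1 with
# baseline-informed priors (level 2); vague normal priors on the group
# locations theta, inverse-gamma(1e-3, 1e-3) on the variances sigma^2 and on
# the shared Student-t df nu (level 3). Sampling is adaptive
# Metropolis-within-Gibbs on unconstrained scales with conjugate updates for
# theta, sigma^2 and k; the posterior, not the sampler, is the contract.

# Internal: flatten a trial table into the arrays the C++ sampler expects.
prepare_fit_data <- function(trials, specs, include_no_feedback = TRUE,
                             baseline_stats = NULL) {
  validate_trials(trials)
  check_specs(specs)
  acq <- trials[trials$phase %in% c("ACQUISITION", "NO_FEEDBACK"), ,
                drop = FALSE]
  if (nrow(acq) == 0) stop("no acquisition-phase trials to fit")
  ids <- unique(acq$participant_id)
  groups <- unique(trials$group[match(ids, trials$participant_id)])
  glev <- intersect(GROUPS, groups)
  tab <- table(factor(trials$group[match(ids, trials$participant_id)],
                      levels = glev))
  if (any(tab < 2))
    stop("need at least 2 participants per group; got: ",
         paste(names(tab), tab, collapse = ", "))

  h <- integer(0); hl <- double(0); hu <- double(0); fc <- double(0)
  obs <- integer(0); upd <- integer(0); off <- integer(0); len <- integer(0)
  muL <- muH <- sdL <- sdH <- double(length(ids))
  for (i in seq_along(ids)) {
    tp <- acq[acq$participant_id == ids[i], , drop = FALSE]
    tp <- tp[order(tp$obstacle_index), , drop = FALSE]
    sp <- spec_for_class(specs, tp$height_class)
    keep_lik <- !is.na(tp$fc_observed) &
      (include_no_feedback | tp$phase != "NO_FEEDBACK")
    off <- c(off, length(h))
    len <- c(len, nrow(tp))
    h <- c(h, as.integer(tp$height_class == "HIGH"))
    hl <- c(hl, sp$h_lower); hu <- c(hu, sp$h_upper)
    fc <- c(fc, ifelse(is.na(tp$fc_observed), 0, tp$fc_observed))
    obs <- c(obs, as.integer(keep_lik))
    # missing trials and excluded bouts freeze the state
    upd <- c(upd, as.integer(keep_lik))
    bs <- baseline_summary(trials, ids[i], baseline_stats)
    muL[i] <- bs["mu_low"]; sdL[i] <- bs["sd_low"]
    muH[i] <- bs["mu_high"]; sdH[i] <- bs["sd_high"]
  }
  grp <- match(trials$group[match(ids, trials$participant_id)], glev) - 1L
  list(h = h, hl = hl, hu = hu, fc = fc, obs = obs, upd = upd,
       off = off, len = len, grp = as.integer(grp),
       n_groups = length(glev), mu_low = muL, sd_low = sdL,
       mu_high = muH, sd_high = sdH, ids = ids, group_levels = glev)
}

# Internal: baseline mean/SD per height for one participant (informative x1
# prior). Falls back to user-supplied stats when no BASELINE phase exists.
baseline_summary <- function(trials, id, baseline_stats = NULL) {
  b <- trials[trials$participant_id == id & trials$phase == "BASELINE" &
                !is.na(trials$fc_observed), , drop = FALSE]
  if (nrow(b) >= 4) {
    lo <- b$fc_observed[b$height_class == "LOW"]
    hi <- b$fc_observed[b$height_class == "HIGH"]
    if (length(lo) >= 2 && length(hi) >= 2)
      return(c(mu_low = mean(lo), sd_low = max(sd(lo), 1e-3),
               mu_high = mean(hi), sd_high = max(sd(hi), 1e-3)))
  }
  if (!is.null(baseline_stats)) {
    r <- baseline_stats[baseline_stats$participant_id == id, , drop = FALSE]
    if (nrow(r) == 1)
      return(c(mu_low = r$mu_low, sd_low = r$sd_low,
               mu_high = r$mu_high, sd_high = r$sd_high))
  }
  stop("no baseline records (and no baseline_stats) for participant ", id)
}

#' Pointwise Student-t log-likelihood for one participant
#'
#' Runs the deterministic forward model over the participant's acquisition
#' trials and evaluates the Student-t log density of each observed clearance
#' centered at the model output. Missing observations contribute zero and
#' freeze the state.
#'
#' @param trials Trial records for a single participant (acquisition phases),
#'   sorted by `obstacle_index`.
#' @param params List with `B`, `q`, `tau`, `x1_low`, `x1_high`.
#' @param nu Student-t degrees of freedom.
#' @param specs Obstacle definitions.
#' @param variant Motor-output variant.
#' @param include_no_feedback Include the no-feedback bout in the likelihood
#'   (and in state updates)?
#' @return List with `total` (scalar log-likelihood) and `pointwise` (per
#'   trial; 0 for missing observations).
#' @export
log_likelihood <- function(trials, params, nu,
                           specs = default_obstacle_specs(),
                           variant = c("dot", "select"),
                           include_no_feedback = TRUE) {
  variant <- match.arg(variant)
  if (length(unique(trials$participant_id)) != 1)
    stop("log_likelihood expects a single participant")
  if (is.unsorted(trials$obstacle_index, strictly = TRUE))
    stop("trials must be sorted by obstacle_index (strictly increasing)")
  sp <- spec_for_class(specs, trials$height_class)
  keep <- !is.na(trials$fc_observed) &
    (include_no_feedback | trials$phase != "NO_FEEDBACK")
  fwd <- forward_sim_cpp(as.integer(trials$height_class == "HIGH"),
                         sp$h_lower, sp$h_upper, params$B, params$q,
                         params$x1_low, params$x1_high,
                         variant == "select", keep)
  pw <- rep(0, nrow(trials))
  r <- (trials$fc_observed - fwd$fc_est)[keep]
  pw[keep] <- dt(r / params$tau, df = nu, log = TRUE) - log(params$tau)
  list(total = sum(pw), pointwise = pw)
}

#' Fit the hierarchical Bayesian state-space model by MCMC
#'
#' Estimates per-participant learning rates, interference, observation
#' scales, baseline scaling and initial states, together with per-group
#' hyper-parameters and a shared Student-t degrees of freedom, from
#' acquisition-phase trial records. Defaults mirror the original protocol
#' (3 chains x 20,000 iterations, 10,000 burn-in, thinning 10: 3,000
#' retained draws); tests use reduced settings with the same diagnostics.
#'
#' @param trials Trial-record table (see [read_trials()]); must contain
#'   acquisition-phase rows and, for the initial-state priors, BASELINE rows
#'   per participant (or supply `baseline_stats`).
#' @param model `"full"` (B and q), `"b_only"` (q fixed at 0) or `"q_only"`
#'   (one learning rate shared by all participants, estimated).
#' @param variant Motor-output variant, `"dot"` (default) or `"select"`.
#' @param specs Obstacle definitions.
#' @param chains,iter,burn_in,thin MCMC protocol; retained draws per chain =
#'   `(iter - burn_in) / thin`.
#' @param seed Integer seed; runs are reproducible given identical settings.
#' @param include_no_feedback Logical; include the no-feedback bout (errors
#'   remained visible there) in likelihood and state updates. Default TRUE.
#' @param baseline_stats Optional per-participant baseline summaries
#'   (`participant_id`, `mu_low`, `sd_low`, `mu_high`, `sd_high`) used when
#'   BASELINE records are absent.
#' @param likelihood_weight Likelihood tempering weight; 0 gives
#'   prior-predictive sampling (used for prior checks).
#' @return A `loco_fit` object: `draws` (array draw x chain x parameter),
#'   `participants`, `group_levels`, `model`, `variant`, `mcmc` settings,
#'   and the prepared data (for WAIC).
#' @export
loco_fit <- function(trials, model = c("full", "b_only", "q_only"),
                     variant = c("dot", "select"),
                     specs = default_obstacle_specs(),
                     chains = 3, iter = 20000, burn_in = 10000, thin = 10,
                     seed = 1L, include_no_feedback = TRUE,
                     baseline_stats = NULL, likelihood_weight = 1) {
  model <- match.arg(model)
  variant <- match.arg(variant)
  stopifnot(chains >= 1, iter > burn_in, thin >= 1)
  d <- prepare_fit_data(trials, specs, include_no_feedback, baseline_stats)
  model_code <- match(model, c("full", "b_only", "q_only")) - 1L
  prior <- list(theta_sd = sqrt(1000), sig_a0 = 1e-3, sig_b0 = 1e-3,
                tau_sd = sqrt(1000), k_sd = sqrt(1000), nu_floor = 1)

  n_p <- length(d$ids); n_g <- d$n_groups
  par_names <- c(
    if (model != "q_only")
      as.vector(rbind(paste0("theta_B[", d$group_levels, "]"),
                      paste0("sigma_B[", d$group_levels, "]"))),
    if (model != "b_only")
      as.vector(rbind(paste0("theta_q[", d$group_levels, "]"),
                      paste0("sigma_q[", d$group_levels, "]"))),
    "nu",
    if (model == "q_only") "b_shared",
    as.vector(vapply(d$ids, function(id)
      paste0(c("B[", "q[", "tau[", "k[", "x1_low[", "x1_high["), id, "]"),
      character(6))))

  n_keep <- (iter - burn_in) %/% thin
  draws <- array(NA_real_, c(n_keep, chains, length(par_names)),
                 dimnames = list(NULL, paste0("chain", seq_len(chains)),
                                 par_names))
  chain_seeds <- derive_seeds(seed, chains)
  for (ch in seq_len(chains)) {
    set.seed(chain_seeds[ch])
    init <- list(
      b = qlogis(0.1) + 0.5 * rnorm(n_p),
      u = qlogis(0.3) + 0.5 * rnorm(n_p),
      tau = 0.03 * exp(0.2 * rnorm(n_p)),
      k = rep(1, n_p),
      x1_low = d$mu_low + 0.1 * d$sd_low * rnorm(n_p),
      x1_high = d$mu_high + 0.1 * d$sd_high * rnorm(n_p),
      theta_B = rep(qlogis(0.1), n_g), sig2_B = rep(1, n_g),
      theta_q = rep(qlogis(0.3), n_g), sig2_q = rep(1, n_g),
      nu = exp(log(10) + 0.3 * rnorm(1)))
    res <- run_chain_cpp(d, init, prior, model_code, variant == "select",
                         as.integer(iter), as.integer(burn_in),
                         as.integer(thin), likelihood_weight)
    draws[, ch, ] <- res$draws[seq_len(n_keep), , drop = FALSE]
  }

  structure(list(
    draws = draws,
    participants = data.frame(participant_id = d$ids,
                              group = d$group_levels[d$grp + 1L],
                              stringsAsFactors = FALSE),
    group_levels = d$group_levels,
    model = model, variant = variant,
    include_no_feedback = include_no_feedback,
    mcmc = list(chains = chains, iter = iter, burn_in = burn_in,
                thin = thin, seed = seed, n_retained = n_keep * chains),
    data = d, data_hash = fnv1a_hash(d[c("h", "hl", "hu", "fc", "obs",
                                         "off", "len")])),
    class = "loco_fit")
}

#' @export
print.loco_fit <- function(x, ...) {
  cat("Hierarchical Bayesian state-space fit (", x$model, ", ",
      x$variant, " output)\n", sep = "")
  cat("  participants:", nrow(x$participants), "in groups",
      paste(x$group_levels, collapse = ", "), "\n")
  cat("  retained draws:", x$mcmc$n_retained,
      sprintf("(%d chains x %d)", x$mcmc$chains,
              x$mcmc$n_retained / x$mcmc$chains), "\n")
  dg <- diagnose(x)
  cat("  max split R-hat:", format(max(dg$rhat, na.rm = TRUE), digits = 4),
      if (attr(dg, "converged")) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' Extract posterior draws as a matrix
#'
#' @param fit A `loco_fit`.
#' @param pars Optional character vector of parameter names.
#' @return Matrix (all chains stacked) with one column per parameter.
#' @export
posterior_matrix <- function(fit, pars = NULL) {
  stopifnot(inherits(fit, "loco_fit"))
  d <- fit$draws
  m <- do.call(rbind, lapply(seq_len(dim(d)[2]), function(ch) d[, ch, ]))
  colnames(m) <- dimnames(d)[[3]]
  if (!is.null(pars)) {
    miss <- setdiff(pars, colnames(m))
    if (length(miss)) stop("unknown parameters: ", paste(miss, collapse = ", "))
    m <- m[, pars, drop = FALSE]
  }
  m
}

#' Posterior medians of the per-participant parameters
#'
#' @param fit A `loco_fit`.
#' @return `data.frame` with `participant_id`, `group`, and posterior-median
#'   `B`, `q`, `tau`, `k`, `x1_low`, `x1_high`.
#' @export
participant_medians <- function(fit) {
  m <- posterior_matrix(fit)
  ids <- fit$participants$participant_id
  out <- fit$participants
  for (p in c("B", "q", "tau", "k", "x1_low", "x1_high"))
    out[[p]] <- vapply(ids, function(id)
      median(m[, paste0(p, "[", id, "]")]), numeric(1))
  rownames(out) <- NULL
  out
}
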