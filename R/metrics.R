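# Behavioral performance metrics: per-trial performance error, online
# improvement (no-feedback vs baseline), overnight retention (Day-2 vs end
# of practice) and the learning-parameter association regressions.

#' Per-trial performance error
#'
#' Absolute distance from the foot clearance to the nearer success-range
#' threshold; zero inside the range. Equals `|compute_error(fc, spec)|`.
#'
#' @param fc Foot clearance (meters); vectorized.
#' @param spec An [obstacle_spec()] row.
#' @return Non-negative error in meters.
#' @export
performance_error <- function(fc, spec) {
  abs(compute_error(fc, spec))
}

#' Behavioral summary for one participant
#'
#' Phase-by-height mean performance errors plus the two learning outcomes:
#' online improvement (mean error during the no-feedback bout minus
#' baseline; negative = improvement) and overnight retention delta (Day-2
#' retention minus end of practice, the final acquisition bout; positive =
#' forgetting). Phases absent from the data yield `NA` summaries rather
#' than errors.
#'
#' @param trials Trial records for a single participant.
#' @param specs Obstacle definitions.
#' @param end_bout Bout index defining "end of practice" (default: the last
#'   bout present in the acquisition phase).
#' @return A one-row `data.frame`: `participant_id`, `group`, per-phase
#'   mean errors (`err_baseline`, `err_no_feedback`, `err_end_practice`,
#'   `err_retention`), `online_improvement`, `retention_delta`.
#' @export
summarize_participant <- function(trials, specs = default_obstacle_specs(),
                                  end_bout = NULL) {
  if (length(unique(trials$participant_id)) != 1)
    stop("summarize_participant expects a single participant")
  check_specs(specs)
  err <- function(rows) {
    if (nrow(rows) == 0) return(NA_real_)
    sp <- spec_for_class(specs, rows$height_class)
    mean(abs(compute_error(rows$fc_observed, sp)))
  }
  ok <- !is.na(trials$fc_observed)
  base <- trials[ok & trials$phase == "BASELINE", , drop = FALSE]
  nofb <- trials[ok & trials$phase == "NO_FEEDBACK", , drop = FALSE]
  acq <- trials[ok & trials$phase %in% c("ACQUISITION", "NO_FEEDBACK"), ,
                drop = FALSE]
  ret <- trials[ok & trials$phase == "RETENTION", , drop = FALSE]
  if (is.null(end_bout) && nrow(acq) > 0) end_bout <- max(acq$bout)
  endp <- acq[acq$bout == (end_bout %||% -1L), , drop = FALSE]

  e_base <- err(base); e_nofb <- err(nofb)
  e_end <- err(endp); e_ret <- err(ret)
  data.frame(participant_id = trials$participant_id[1],
             group = trials$group[1],
             err_baseline = e_base, err_no_feedback = e_nofb,
             err_end_practice = e_end, err_retention = e_ret,
             online_improvement = e_nofb - e_base,
             retention_delta = e_ret - e_end,
             stringsAsFactors = FALSE)
}

#' Behavioral summaries for a whole trial table
#'
#' @param trials Trial-record table (multiple participants).
#' @param specs Obstacle definitions.
#' @param fit Optional `loco_fit`; when given, adds posterior-median `B` and
#'   `q` and the model-based performance error over the final practice bout
#'   (`model_end_error`), computed from the posterior-median parameters'
#'   noiseless forward trajectory.
#' @return `data.frame`, one row per participant.
#' @export
summarize_cohort <- function(trials, specs = default_obstacle_specs(),
                             fit = NULL) {
  ids <- unique(trials$participant_id)
  out <- do.call(rbind, lapply(ids, function(id)
    summarize_participant(trials[trials$participant_id == id, , drop = FALSE],
                          specs)))
  if (!is.null(fit)) {
    med <- participant_medians(fit)
    out <- merge(out, med[, c("participant_id", "B", "q")],
                 by = "participant_id", sort = FALSE)
    out$model_end_error <- vapply(out$participant_id, function(id)
      model_end_error(trials, med[med$participant_id == id, ], specs,
                      fit$variant), numeric(1))
  }
  rownames(out) <- NULL
  out
}

# Internal: mean model-implied performance error over the final practice
# bout, from posterior-median parameters.
model_end_error <- function(trials, pars, specs, variant) {
  acq <- trials[trials$participant_id == pars$participant_id &
                  trials$phase %in% c("ACQUISITION", "NO_FEEDBACK"), ,
                drop = FALSE]
  if (nrow(acq) == 0) return(NA_real_)
  acq <- acq[order(acq$obstacle_index), , drop = FALSE]
  sim <- simulate_sequence(list(B = pars$B, q = pars$q, tau = pars$tau,
                                x1_low = pars$x1_low, x1_high = pars$x1_high),
                           acq$height_class, specs, noise = "none",
                           variant = variant)
  last <- acq$bout == max(acq$bout)
  sp <- spec_for_class(specs, acq$height_class[last])
  mean(abs(compute_error(sim$fc_est[last], sp)))
}

#' Association between learning parameters and behavioral outcomes
#'
#' Ordinary least-squares fits of (a) online improvement on learning rate
#' with a group interaction, (b) overnight retention delta on interference
#' with a group interaction, and (c) Day-2 retention error on the
#' model-based end-of-acquisition error. With one summary row per
#' participant these fixed-effects fits mirror the structure of the
#' original mixed-model contrasts.
#'
#' @param summaries Output of [summarize_cohort()] including `B`, `q` (and
#'   `model_end_error` for model (c)).
#' @return Named list of regression reports; each has `coefficients` (a
#'   table with estimates, t statistics and p values), `adj_r_squared`,
#'   `n`, and the model `formula`.
#' @export
association_models <- function(summaries) {
  need <- c("online_improvement", "retention_delta", "B", "q", "group")
  miss <- setdiff(need, names(summaries))
  if (length(miss)) stop("summaries missing columns: ",
                         paste(miss, collapse = ", "))
  if (length(unique(summaries$group)) < 2)
    stop("association models need both groups")
  tab <- table(summaries$group)
  if (any(tab < 3)) stop("need at least 3 participants per group")
  out <- list(
    improvement = ols_report(online_improvement ~ B * group, summaries),
    retention = ols_report(retention_delta ~ q * group, summaries))
  if ("model_end_error" %in% names(summaries))
    out$end_error <- ols_report(err_retention ~ model_end_error, summaries)
  out
}

# Internal: lm with explicit rank-deficiency reporting.
ols_report <- function(formula, data) {
  data <- data[complete.cases(data[, all.vars(formula), drop = FALSE]), ,
               drop = FALSE]
  fit <- lm(formula, data = data)
  if (fit$rank < ncol(stats::model.matrix(fit))) {
    bad <- names(which(is.na(coef(fit))))
    stop("rank-deficient design; collinear terms: ",
         paste(bad, collapse = ", "))
  }
  s <- summary(fit)
  list(formula = deparse(formula),
       coefficients = as.data.frame(s$coefficients),
       adj_r_squared = s$adj.r.squared,
       n = nrow(data))
}
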