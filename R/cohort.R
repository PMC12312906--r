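#' Population-level generating parameters for one group
#'
#' Individual learning rates and interference values are generated as
#' `sigmoid(Normal(theta, sigma))` on the logit scale, so `sigmoid(theta)`
#' is the population median on the unit scale. Observation noise is
#' Student-t with participant scales `tau` (log-normal across participants)
#' and shared degrees of freedom `nu`.
#'
#' Defaults mirror the estimates reported for this task: control median
#' learning rate 0.08 and interference 0.36; the PD presets in
#' [default_populations()] use 0.14 and 0.45. `tau_meanlog` defaults so that
#' the observation SD is about 0.03 m at `nu = 5`
#' (`sd = tau * sqrt(nu / (nu - 2))`).
#'
#' @param group `"CONTROL"` or `"PD"`.
#' @param theta_B,sigma_B Location/spread of the logit-scale learning rate.
#' @param theta_q,sigma_q Location/spread of the logit-scale interference.
#' @param nu Student-t degrees of freedom (> 2 for finite observation SD).
#' @param tau_meanlog,tau_sdlog Log-normal parameters of the per-participant
#'   observation scale (meters).
#' @return A list with class `population_params`.
#' @export
population_params <- function(group = c("CONTROL", "PD"),
                              theta_B = qlogis(0.08), sigma_B = 0.5,
                              theta_q = qlogis(0.36), sigma_q = 0.8,
                              nu = 5,
                              tau_meanlog = log(0.023), tau_sdlog = 0.25) {
  group <- match.arg(group)
  stopifnot(sigma_B > 0, sigma_q > 0, nu > 0, tau_sdlog >= 0)
  structure(list(group = group, theta_B = theta_B, sigma_B = sigma_B,
                 theta_q = theta_q, sigma_q = sigma_q, nu = nu,
                 tau_meanlog = tau_meanlog, tau_sdlog = tau_sdlog),
            class = "population_params")
}

#' Default generating populations (control and PD)
#'
#' Medians: learning rate 0.08 (control) vs 0.14 (PD); interference 0.36 vs
#' 0.45.
#'
#' @return Named list with elements `control` and `pd`.
#' @export
default_populations <- function() {
  list(control = population_params("CONTROL"),
       pd = population_params("PD", theta_B = qlogis(0.14),
                              theta_q = qlogis(0.45)))
}

#' Study design for a synthetic cohort
#'
#' Defaults emulate the two-day protocol: per-height baseline bouts,
#' 192 acquisition obstacles in six 32-obstacle bouts with the fifth bout
#' delivered without performance feedback, and Day-2 retention trials.
#' Baseline clearance means/SDs are stand-ins (the source study does not
#' report them) and are configurable.
#'
#' @param n_control,n_pd Participants per group (defaults 20 and 15).
#' @param n_baseline_per_height Baseline crossings per obstacle height.
#' @param n_bouts,bout_size Acquisition structure; total obstacles =
#'   `n_bouts * bout_size` (default 6 x 32 = 192).
#' @param no_feedback_bout Index of the acquisition bout delivered without
#'   performance feedback (default 5).
#' @param n_retention_per_height Day-2 retention crossings per height.
#' @param baseline_mean,baseline_sd Named numeric (LOW, HIGH): baseline foot
#'   clearance above the obstacle top, meters.
#' @param forgetting Retention forgetting factor in `[0, 1]`: 1 carries the
#'   end-of-acquisition state into Day 2 unchanged; smaller values shrink the
#'   state toward the baseline clearance (partial overnight forgetting).
#' @param max_run Longest allowed run of same-height obstacles in a schedule.
#' @return A list with class `cohort_design`.
#' @export
cohort_design <- function(n_control = 20, n_pd = 15,
                          n_baseline_per_height = 32,
                          n_bouts = 6, bout_size = 32,
                          no_feedback_bout = 5,
                          n_retention_per_height = 16,
                          baseline_mean = c(LOW = 0.15, HIGH = 0.10),
                          baseline_sd = c(LOW = 0.04, HIGH = 0.04),
                          forgetting = 1.0, max_run = 4) {
  stopifnot(n_control >= 1, n_pd >= 1, bout_size %% 2 == 0,
            no_feedback_bout >= 1, no_feedback_bout <= n_bouts,
            forgetting >= 0, forgetting <= 1, max_run >= 1)
  structure(list(n_control = n_control, n_pd = n_pd,
                 n_baseline_per_height = n_baseline_per_height,
                 n_bouts = n_bouts, bout_size = bout_size,
                 no_feedback_bout = no_feedback_bout,
                 n_retention_per_height = n_retention_per_height,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 forgetting = forgetting, max_run = max_run),
            class = "cohort_design")
}

# Internal: derive independent sub-seeds from one master seed.
# A fixed linear-congruential scramble keeps every derived seed < 2^31 and
# documented; all package randomness flows from the master seed this way.
derive_seeds <- function(seed, n) {
  s <- as.double(seed %% 2147483647L)
  out <- integer(n)
  for (i in seq_len(n)) {
    s <- (s * 48271) %% 2147483647
    out[i] <- as.integer(s)
  }
  out
}

#' Draw per-participant parameters from a population
#'
#' `B_p = sigmoid(Normal(theta_B, sigma_B))`, `q_p =
#' sigmoid(Normal(theta_q, sigma_q))`, `tau_p` log-normal, `k_p = 1`
#' (baseline scaling), and initial states equal to the participant's
#' baseline clearance mean per height.
#'
#' @param pop A [population_params()].
#' @param n Number of participants.
#' @param design A [cohort_design()] (supplies baseline means/SDs).
#' @param seed Integer seed; draws are reproducible given the seed.
#' @return `data.frame` with one row per participant: `B`, `q`, `tau`, `k`,
#'   `x1_low`, `x1_high`, `nu`, `group`.
#' @export
draw_participants <- function(pop, n, design = cohort_design(), seed = 1L) {
  stopifnot(inherits(pop, "population_params"), n >= 1)
  set.seed(seed)
  B <- plogis(rnorm(n, pop$theta_B, pop$sigma_B))
  q <- plogis(rnorm(n, pop$theta_q, pop$sigma_q))
  tau <- exp(rnorm(n, pop$tau_meanlog, pop$tau_sdlog))
  base_low <- rnorm(n, design$baseline_mean[["LOW"]],
                    design$baseline_sd[["LOW"]])
  base_high <- rnorm(n, design$baseline_mean[["HIGH"]],
                     design$baseline_sd[["HIGH"]])
  # keep baseline clearances physically sensible (above the success range)
  base_low <- pmax(base_low, 0.02)
  base_high <- pmax(base_high, 0.01)
  data.frame(B = B, q = q, tau = tau, k = 1,
             x1_low = base_low, x1_high = base_high,
             nu = pop$nu, group = pop$group, stringsAsFactors = FALSE)
}

#' Generate a balanced pseudorandom obstacle schedule
#'
#' Each acquisition bout contains exactly `bout_size / 2` LOW and HIGH
#' obstacles, interleaved at random subject to a maximum run length of
#' `design$max_run` same-height obstacles (checked across bout boundaries).
#'
#' @param design A [cohort_design()].
#' @param seed Integer seed.
#' @return `data.frame` with columns `bout`, `obstacle_index` (1..N over the
#'   whole acquisition phase), `height_class`.
#' @export
generate_schedule <- function(design = cohort_design(), seed = 1L) {
  stopifnot(inherits(design, "cohort_design"))
  if (design$bout_size %% 2 != 0) stop("bout_size must be even")
  set.seed(seed)
  half <- design$bout_size / 2
  repeat {
    hc <- unlist(lapply(seq_len(design$n_bouts), function(b)
      sample(rep(HEIGHT_CLASSES, half))))
    r <- rle(hc)
    if (max(r$lengths) <= design$max_run) break
  }
  data.frame(bout = rep(seq_len(design$n_bouts), each = design$bout_size),
             obstacle_index = seq_along(hc), height_class = hc,
             stringsAsFactors = FALSE)
}

#' Generate a complete synthetic two-group study
#'
#' Emits BASELINE records (Student-t noise around each participant's
#' baseline clearance, no learning), ACQUISITION records simulated through
#' the state-space model (the no-feedback bout is phase `NO_FEEDBACK`; the
#' learner still updates there, since errors remain visible), and RETENTION
#' records generated from the end-of-acquisition state (optionally shrunk
#' toward baseline by the design's forgetting factor) with no learning.
#'
#' @param pop_control,pop_pd [population_params()] for the two groups.
#' @param design A [cohort_design()].
#' @param specs Obstacle definitions.
#' @param seed Master seed; all stage seeds are derived from it.
#' @param variant Motor-output variant passed to the simulator.
#' @return A list with class `cohort`: `trials` (trial records), `truth`
#'   (per-participant generating parameters), `populations`, `design`,
#'   `specs`, `seed`, `variant`.
#' @export
generate_cohort <- function(pop_control = default_populations()$control,
                            pop_pd = default_populations()$pd,
                            design = cohort_design(),
                            specs = default_obstacle_specs(),
                            seed = 1L, variant = c("dot", "select")) {
  variant <- match.arg(variant)
  check_specs(specs)
  seeds <- derive_seeds(seed, 4)
  ctrl <- draw_participants(pop_control, design$n_control, design, seeds[1])
  pd <- draw_participants(pop_pd, design$n_pd, design, seeds[2])
  truth <- rbind(ctrl, pd)
  truth$participant_id <- sprintf("%s%02d", ifelse(truth$group == "CONTROL",
                                                   "C", "P"),
                                  c(seq_len(nrow(ctrl)), seq_len(nrow(pd))))
  truth <- truth[, c("participant_id", "group", "B", "q", "tau", "k",
                     "x1_low", "x1_high", "nu")]
  schedule <- generate_schedule(design, seeds[3])

  pseeds <- derive_seeds(seeds[4], 3 * nrow(truth))
  rows <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    rows[[i]] <- simulate_participant(tr, schedule, design, specs,
                                      pseeds[(3 * i - 2):(3 * i)], variant)
  }
  trials <- do.call(rbind, rows)
  rownames(trials) <- NULL
  structure(list(trials = trials, truth = truth,
                 populations = list(control = pop_control, pd = pop_pd),
                 design = design, specs = specs, seed = seed,
                 variant = variant),
            class = "cohort")
}

# Internal: negative simulated clearances are collisions; they are recorded
# as missing observations (the schema requires fc >= 0) and — matching the
# estimator's missing-data rule — freeze the learner's state on that trial.
censor_collisions <- function(fc) ifelse(fc < 0, NA_real_, fc)

# Internal: all phases for one participant.
simulate_participant <- function(tr, schedule, design, specs, seeds,
                                 variant) {
  nu <- tr$nu
  rec <- function(phase, bout, idx, hc, fc) {
    data.frame(participant_id = tr$participant_id, group = tr$group,
               phase = phase, bout = bout, obstacle_index = idx,
               height_class = hc, fc_observed = fc,
               stringsAsFactors = FALSE)
  }

  # BASELINE: noisy crossings around the habitual clearance, no learning
  set.seed(seeds[1])
  nb <- design$n_baseline_per_height
  base <- rbind(
    rec("BASELINE", 0L, seq_len(nb), "LOW",
        censor_collisions(tr$x1_low + tr$tau * stats::rt(nb, df = nu))),
    rec("BASELINE", 0L, nb + seq_len(nb), "HIGH",
        censor_collisions(tr$x1_high + tr$tau * stats::rt(nb, df = nu))))

  # ACQUISITION: state-space simulation with Student-t observation noise;
  # collision trials (negative draw) are missing and freeze the state
  set.seed(seeds[2])
  n_acq <- nrow(schedule)
  noise <- tr$tau * stats::rt(n_acq, df = nu)
  x <- c(tr$x1_low, tr$x1_high)
  fc_obs <- numeric(n_acq)
  sp <- spec_for_class(specs, schedule$height_class)
  for (t in seq_len(n_acq)) {
    hc <- schedule$height_class[t]
    fe <- motor_output(x[1], x[2], hc, tr$q, variant)
    ob <- fe + noise[t]
    if (ob < 0) {
      fc_obs[t] <- NA_real_
    } else {
      fc_obs[t] <- ob
      e <- compute_error(fe, sp[t, ])
      x <- state_update(x[1], x[2], e, hc, tr$B, tr$q)
    }
  }
  phase <- ifelse(schedule$bout == design$no_feedback_bout,
                  "NO_FEEDBACK", "ACQUISITION")
  acq <- rec(phase, schedule$bout, schedule$obstacle_index,
             schedule$height_class, fc_obs)

  # RETENTION: carry (possibly decayed) final state, no further learning
  f <- design$forgetting
  x_end <- x
  x_ret <- c(tr$x1_low, tr$x1_high) + f * (x_end - c(tr$x1_low, tr$x1_high))
  set.seed(seeds[3])
  nr <- design$n_retention_per_height
  hc_ret <- sample(rep(HEIGHT_CLASSES, nr))
  out_ret <- if (variant == "select") {
    ifelse(hc_ret == "LOW", x_ret[1], x_ret[2])
  } else {
    ifelse(hc_ret == "LOW", x_ret[1] + tr$q * x_ret[2],
           tr$q * x_ret[1] + x_ret[2])
  }
  fc_ret <- censor_collisions(out_ret + tr$tau * stats::rt(2 * nr, df = nu))
  ret <- rec("RETENTION", 0L, seq_len(2 * nr), hc_ret, fc_ret)

  rbind(base, acq, ret)
}
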