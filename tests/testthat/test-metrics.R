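low_spec <- obstacle_spec("LOW", 0.05, 0.05, 0.09)
high_spec <- obstacle_spec("HIGH", 0.18, 0.01, 0.05)

test_that("performance error is |dead-zone error| everywhere", {
  expect_equal(performance_error(0.12, low_spec), 0.03)
  expect_equal(performance_error(0.07, low_spec), 0)
  expect_equal(performance_error(0.00, high_spec), 0.01)
  fc <- seq(-0.05, 0.4, by = 0.003)
  expect_equal(performance_error(fc, low_spec),
               abs(compute_error(fc, low_spec)))
  expect_equal(performance_error(fc, high_spec),
               abs(compute_error(fc, high_spec)))
})

make_trials <- function(id, phase, hc, fc, bout = 0L) {
  data.frame(participant_id = id, group = "CONTROL", phase = phase,
             bout = bout, obstacle_index = seq_along(fc), height_class = hc,
             fc_observed = fc, stringsAsFactors = FALSE)
}

test_that("participant summary reproduces hand-computed deltas", {
  # baseline mean error 0.10 (fc 0.19 on LOW: 0.19 - 0.09), no-feedback
  # mean error 0.02: improvement = -0.08 m
  tr <- rbind(
    make_trials("S1", "BASELINE", "LOW", rep(0.19, 8)),
    make_trials("S1", "ACQUISITION", "LOW", rep(0.12, 8), bout = 1L),
    make_trials("S1", "NO_FEEDBACK", "LOW", rep(0.11, 8), bout = 2L),
    make_trials("S1", "RETENTION", "LOW", rep(0.13, 8)))
  tr$obstacle_index <- ave(tr$obstacle_index, tr$phase, FUN = seq_along)
  s <- summarize_participant(tr)
  expect_equal(s$err_baseline, 0.10)
  expect_equal(s$err_no_feedback, 0.02)
  expect_equal(s$online_improvement, -0.08)
  # end of practice = final acquisition bout (bout 2 here, the NO_FEEDBACK
  # rows are part of acquisition)
  expect_equal(s$err_end_practice, 0.02)
  expect_equal(s$retention_delta, 0.04 - 0.02)

  # all-inside-range trials: zero improvement
  tr0 <- rbind(make_trials("S2", "BASELINE", "LOW", rep(0.07, 6)),
               make_trials("S2", "NO_FEEDBACK", "LOW", rep(0.06, 6),
                           bout = 2L))
  s0 <- summarize_participant(tr0)
  expect_equal(s0$online_improvement, 0)

  # order invariance within phases
  shuf <- tr[sample(nrow(tr)), ]
  expect_equal(summarize_participant(shuf), s)

  # missing phases give NA fields, not errors
  s_part <- summarize_participant(make_trials("S3", "BASELINE", "LOW",
                                              rep(0.12, 4)))
  expect_true(is.na(s_part$online_improvement))
  expect_true(is.na(s_part$retention_delta))
})

test_that("forgetting < 1 produces positive retention deltas", {
  pop <- population_params("CONTROL", tau_meanlog = log(0.002),
                           tau_sdlog = 0, theta_q = -12, sigma_q = 1e-9,
                           theta_B = qlogis(0.3), sigma_B = 0.1)
  des <- small_design(forgetting = 0.2)
  ch <- generate_cohort(pop, population_params("PD",
                                               tau_meanlog = log(0.002),
                                               tau_sdlog = 0,
                                               theta_q = -12,
                                               sigma_q = 1e-9,
                                               theta_B = qlogis(0.3),
                                               sigma_B = 0.1),
                        des, seed = 91)
  summ <- summarize_cohort(ch$trials, ch$specs)
  expect_gt(mean(summ$retention_delta > 0), 0.8)
})

test_that("association models recover exact linear structure", {
  set.seed(92)
  n <- 20
  summ <- data.frame(
    participant_id = sprintf("S%02d", 1:n),
    group = rep(c("CONTROL", "PD"), each = n / 2),
    B = runif(n, 0.02, 0.3), q = runif(n),
    err_retention = runif(n, 0, 0.1),
    stringsAsFactors = FALSE)
  gpd <- as.numeric(summ$group == "PD")
  eps <- rnorm(n, 0, 1e-9)
  summ$online_improvement <- -0.1 + 0.5 * summ$B - 0.02 * gpd -
    0.3 * summ$B * gpd + eps
  summ$retention_delta <- 0.02 + 0.1 * summ$q + 0.01 * gpd +
    0.05 * summ$q * gpd + eps

  rep <- association_models(summ)
  co <- rep$improvement$coefficients
  expect_equal(co["B", "Estimate"], 0.5, tolerance = 1e-5)
  expect_equal(co["B:groupPD", "Estimate"], -0.3, tolerance = 1e-5)
  expect_gt(rep$improvement$adj_r_squared, 0.999)
  co2 <- rep$retention$coefficients
  expect_equal(co2["q", "Estimate"], 0.1, tolerance = 1e-5)
  expect_gt(rep$retention$adj_r_squared, 0.999)

  # degenerate design: constant predictor is collinear with the intercept
  bad <- summ
  bad$q <- 0.5
  expect_error(association_models(bad), "collinear")

  # too few participants per group
  expect_error(association_models(summ[c(1:3, 11:12), ]), "at least 3")
})

test_that("interaction p-values are near-uniform under a permuted null", {
  set.seed(93)
  n <- 24
  pvals <- replicate(150, {
    summ <- data.frame(
      participant_id = sprintf("S%02d", 1:n),
      group = rep(c("CONTROL", "PD"), each = n / 2),
      B = runif(n), q = runif(n),
      online_improvement = rnorm(n), retention_delta = rnorm(n),
      stringsAsFactors = FALSE)
    rep <- association_models(summ)
    rep$retention$coefficients["q:groupPD", "Pr(>|t|)"]
  })
  expect_gt(mean(pvals), 0.4)
  expect_lt(mean(pvals), 0.6)
  expect_lt(mean(pvals < 0.05), 0.12)
})

test_that("model-based end error is computed from posterior medians", {
  ch <- generate_cohort(design = small_design(), seed = 94)
  fit <- quick_fit(ch$trials)
  summ <- summarize_cohort(ch$trials, ch$specs, fit = fit)
  expect_true(all(c("B", "q", "model_end_error") %in% names(summ)))
  expect_true(all(summ$model_end_error >= 0))
  expect_equal(nrow(summ), 12)
  # day-2 error should track model end error reasonably (same state)
  expect_gt(cor(summ$model_end_error, summ$err_retention), 0)
})
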