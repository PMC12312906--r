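make_small_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ch <- generate_cohort(design = small_design(), seed = 21)
      cache <<- list(cohort = ch, fit = quick_fit(ch$trials))
    }
    cache
  }
})

test_that("single-participant log-likelihood matches closed forms", {
  ch <- generate_cohort(design = small_design(), seed = 22)
  id <- ch$truth$participant_id[1]
  tr <- ch$trials[ch$trials$participant_id == id &
                    ch$trials$phase %in% c("ACQUISITION", "NO_FEEDBACK"), ]
  tr <- tr[order(tr$obstacle_index), ]
  p <- as.list(ch$truth[1, c("B", "q", "tau", "x1_low", "x1_high")])

  ll <- log_likelihood(tr, p, nu = 5)
  expect_equal(sum(ll$pointwise), ll$total)
  expect_equal(length(ll$pointwise), nrow(tr))

  # a single trial observed exactly at the model output hits the t mode
  one <- tr[1, ]
  sim1 <- simulate_sequence(p, one$height_class, noise = "none")
  one$fc_observed <- sim1$fc_est[1]
  ll1 <- log_likelihood(one, p, nu = 5)
  expect_equal(ll1$total, dt(0, df = 5, log = TRUE) - log(p$tau))

  # the likelihood flattens as tau grows
  p_wide <- p; p_wide$tau <- 100
  llw <- log_likelihood(tr, p_wide, nu = 5)
  expect_lt(diff(range(llw$pointwise[llw$pointwise != 0])), 1e-4)

  expect_error(log_likelihood(tr[rev(seq_len(nrow(tr))), ], p, nu = 5),
               "sorted")
})

test_that("missing observations contribute nothing and freeze the state", {
  ch <- generate_cohort(design = small_design(), seed = 23)
  id <- ch$truth$participant_id[2]
  tr <- ch$trials[ch$trials$participant_id == id &
                    ch$trials$phase %in% c("ACQUISITION", "NO_FEEDBACK"), ]
  tr <- tr[order(tr$obstacle_index), ]
  p <- as.list(ch$truth[2, c("B", "q", "tau", "x1_low", "x1_high")])
  tr2 <- tr
  tr2$fc_observed[5:8] <- NA
  ll <- log_likelihood(tr2, p, nu = 5)
  expect_true(all(ll$pointwise[5:8] == 0))
})

test_that("fit bookkeeping: retained draws, reproducibility, constraints", {
  sf <- make_small_fit()
  fit <- sf$fit
  expect_equal(dim(fit$draws)[1] * dim(fit$draws)[2],
               2 * (1500 - 800) %/% 2)
  expect_equal(fit$mcmc$n_retained, 700)

  m <- posterior_matrix(fit)
  bq <- m[, grepl("^[Bq]\\[", colnames(m))]
  expect_true(all(bq > 0 & bq < 1))
  expect_true(all(m[, grepl("^tau", colnames(m))] > 0))
  expect_true(all(m[, "nu"] > 1))

  fit2 <- quick_fit(sf$cohort$trials)
  expect_identical(fit$draws, fit2$draws)
})

test_that("fit refuses groups with fewer than 2 participants", {
  ch <- generate_cohort(design = small_design(), seed = 24)
  solo <- ch$trials[ch$trials$participant_id %in%
                      c(paste0("C0", 1:5), "P01"), ]
  expect_error(loco_fit(solo, chains = 2, iter = 200, burn_in = 100),
               "at least 2 participants")
})

test_that("prior-predictive sampling ignores the data", {
  ch <- generate_cohort(design = small_design(), seed = 25)
  fit0 <- loco_fit(ch$trials, chains = 2, iter = 1500, burn_in = 800,
                   thin = 2, seed = 5, likelihood_weight = 0)
  m0 <- posterior_matrix(fit0)
  # tau has a proper half-normal(sd = sqrt(1000)) prior with closed-form
  # quantiles; with the likelihood weighted out the draws must reproduce it
  # (within MCMC error), instead of the ~0.02 m scale the data imply
  tau0 <- as.vector(m0[, grepl("^tau\\[", colnames(m0))])
  hn <- sqrt(1000) * qnorm(c(0.625, 0.75, 0.875))   # HN 25/50/75% quantiles
  q0 <- unname(quantile(tau0, c(0.25, 0.5, 0.75)))
  expect_true(all(abs(q0 / hn - 1) < 0.35))

  sf <- make_small_fit()
  tau1 <- as.vector(posterior_matrix(sf$fit)[, grepl("^tau\\[",
                                                     colnames(m0))])
  expect_lt(median(tau1), 0.1)
})

test_that("R-hat separates mixed from divergent chains", {
  set.seed(61)
  iid <- array(rnorm(4000), c(1000, 4, 1))
  dg <- diagnose(iid)
  expect_lt(dg$rhat[1], 1.01)
  expect_lt(dg$rank_rhat[1], 1.01)
  expect_true(attr(dg, "converged"))

  off <- iid
  off[, 2, 1] <- off[, 2, 1] + 10
  dg2 <- diagnose(off)
  expect_gt(dg2$rhat[1], 1.5)
  expect_false(attr(dg2, "converged"))

  # constant parameter: NA with a warning, not a crash
  const <- array(c(rnorm(200), rep(1, 200)), c(100, 2, 2),
                 dimnames = list(NULL, NULL, c("a", "fixed")))
  expect_warning(dg3 <- diagnose(const), "constant")
  expect_true(is.na(dg3$rhat[dg3$parameter == "fixed"]))

  expect_error(diagnose(array(rnorm(100), c(100, 1, 1))), "2 chains")
  expect_error(rhat(matrix(rnorm(100), ncol = 1)), "2 chains")
})

test_that("WAIC: identical fits tie, penalty is non-negative, hash guards", {
  sf <- make_small_fit()
  fit <- sf$fit
  w <- loco_waic(fit)
  expect_gte(w$p_waic, 0)
  expect_equal(w$waic, -2 * (w$lppd - w$p_waic))

  fit2 <- quick_fit(sf$cohort$trials)
  cmp <- loco_compare(list(a = fit, b = fit2))
  expect_equal(cmp$delta_waic[2], 0)

  other <- generate_cohort(design = small_design(), seed = 99)
  fit3 <- quick_fit(other$trials)
  expect_error(loco_compare(list(fit, fit3)), "identical data")
})

test_that("reduced models keep their contracts", {
  sf <- make_small_fit()
  fb <- quick_fit(sf$cohort$trials, model = "b_only")
  m <- posterior_matrix(fb)
  expect_true(all(m[, grepl("^q\\[", colnames(m))] == 0))
  expect_false(any(grepl("theta_q", colnames(m))))

  fq <- quick_fit(sf$cohort$trials, model = "q_only")
  mq <- posterior_matrix(fq)
  bcols <- mq[, grepl("^B\\[", colnames(mq))]
  expect_true(all(apply(bcols, 1, function(r) all(r == r[1]))))
  expect_true("b_shared" %in% colnames(mq))
})
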