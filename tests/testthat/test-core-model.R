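low_spec <- obstacle_spec("LOW", 0.05, 0.05, 0.09)
high_spec <- obstacle_spec("HIGH", 0.18, 0.01, 0.05)

test_that("dead-zone error covers all three branches and vectorizes", {
  expect_equal(compute_error(0.12, low_spec), -0.03)
  expect_equal(compute_error(0.07, low_spec), 0)
  expect_equal(compute_error(0.03, low_spec), 0.02)
  # closed interval: both thresholds are inside the dead zone
  expect_equal(compute_error(c(0.05, 0.09), low_spec), c(0, 0))
  expect_equal(compute_error(c(0.12, 0.07, 0.03), low_spec),
               c(-0.03, 0, 0.02))
  expect_error(compute_error(NaN, low_spec), "finite")
  expect_error(compute_error(Inf, low_spec), "finite")
})

test_that("context vector routes weights with the LOW component first", {
  expect_equal(context_vector("LOW", 0.5), c(1, 0.5))
  expect_equal(context_vector("HIGH", 0), c(0, 1))
  expect_equal(context_vector("HIGH", 1), c(1, 1))
  expect_error(context_vector("MEDIUM", 0.5))
  expect_error(context_vector("LOW", 1.5))
})

test_that("motor output: dot blends states, select picks the context's", {
  expect_equal(motor_output(0.20, 0.10, "LOW", q = 0), 0.20)
  expect_equal(motor_output(0.20, 0.10, "LOW", q = 0.5), 0.25)
  expect_equal(motor_output(0.20, 0.10, "LOW", q = 0.5, variant = "select"),
               0.20)
  expect_equal(motor_output(0.20, 0.10, "HIGH", q = 0.5), 0.20)
  expect_equal(motor_output(0.20, 0.10, "HIGH", q = 0.5, variant = "select"),
               0.10)
})

test_that("state update is componentwise and conserves in the dead zone", {
  expect_equal(state_update(0.20, 0.10, -0.04, "LOW", B = 0.5, q = 0.5),
               c(0.18, 0.09))
  expect_identical(state_update(0.20, 0.10, 0, "LOW", B = 0.7, q = 0.3),
                   c(0.20, 0.10))
  # full interference keeps equal states equal
  expect_equal(state_update(0.20, 0.20, -0.02, "LOW", B = 1, q = 1),
               c(0.18, 0.18))
})

test_that("noiseless LOW-only sequence follows the geometric closed form", {
  p <- list(B = 0.1, q = 0, tau = 0.01, x1_low = 0.20, x1_high = 0.10)
  sim <- simulate_sequence(p, rep("LOW", 11), noise = "none")
  # after n updates the output is 0.09 + 0.11 * 0.9^n
  expect_equal(sim$fc_est, 0.09 + 0.11 * 0.9^(0:10), tolerance = 1e-14)
  expect_equal(sim$fc_est[11], 0.128354628411, tolerance = 1e-9)
})

test_that("zero learning rate keeps output constant; empty schedule errors", {
  p <- list(B = 0, q = 0.4, tau = 0.01, x1_low = 0.17, x1_high = 0.08)
  sim <- simulate_sequence(p, sample(rep(c("LOW", "HIGH"), 10)),
                           noise = "none")
  expect_true(all(sim$fc_est[sim$height_class == "LOW"] ==
                    sim$fc_est[sim$height_class == "LOW"][1]))
  expect_error(simulate_sequence(p, character(0)), "non-empty")
  expect_error(simulate_sequence(p, c("LOW", "TALL")), "unknown")
})

test_that("simulator matches the naive reference loop to machine precision", {
  set.seed(802)
  sched <- sample(rep(c("LOW", "HIGH"), 16))
  sp <- rbind(low_spec, high_spec)
  for (variant in c("dot", "select")) {
    p <- list(B = 0.14, q = 0.45, tau = 0.01, x1_low = 0.21, x1_high = 0.12)
    sim <- simulate_sequence(p, sched, sp, noise = "none", variant = variant)
    ref <- reference_simulate(p$B, p$q, p$x1_low, p$x1_high, sched,
                              ifelse(sched == "LOW", 0.05, 0.01),
                              ifelse(sched == "LOW", 0.09, 0.05),
                              variant)
    expect_equal(sim$fc_est, ref$fc_est, tolerance = 1e-15)
    expect_equal(sim$error, ref$error, tolerance = 1e-15)
  }
})

test_that("student-t noise is reproducible and only affects fc_obs", {
  p <- list(B = 0.2, q = 0.3, tau = 0.02, nu = 5,
            x1_low = 0.18, x1_high = 0.09)
  sched <- rep(c("LOW", "HIGH"), 20)
  a <- simulate_sequence(p, sched, noise = "student_t", seed = 9)
  b <- simulate_sequence(p, sched, noise = "student_t", seed = 9)
  c0 <- simulate_sequence(p, sched, noise = "none")
  expect_identical(a$fc_obs, b$fc_obs)
  expect_identical(a$fc_est, c0$fc_est)
  expect_false(all(a$fc_obs == a$fc_est))
})

test_that("property: dead-zone trials leave the state exactly unchanged", {
  set.seed(31)
  for (i in 1:200) {
    B <- runif(1); q <- runif(1)
    x <- runif(2, 0, 0.3)
    hc <- sample(c("LOW", "HIGH"), 1)
    sp <- if (hc == "LOW") low_spec else high_spec
    fc <- motor_output(x[1], x[2], hc, q)
    e <- compute_error(fc, sp)
    x2 <- state_update(x[1], x[2], e, hc, B, q)
    if (e == 0) expect_identical(x2, x)
    # boundedness: the active component never moves past the error size
    expect_lte(abs(x2[if (hc == "LOW") 1 else 2] -
                     x[if (hc == "LOW") 1 else 2]), abs(e))
  }
})

test_that("property: full interference with equal starts stays symmetric", {
  set.seed(32)
  sched <- sample(rep(c("LOW", "HIGH"), 50))
  for (i in 1:20) {
    x1 <- runif(1, 0, 0.3)
    p <- list(B = runif(1), q = 1, tau = 0.01, x1_low = x1, x1_high = x1)
    sim <- simulate_sequence(p, sched, noise = "none")
    expect_identical(sim$x_low, sim$x_high)
  }
})

test_that("property: with q = 0 the above-range gap decays by (1 - B)", {
  set.seed(33)
  for (i in 1:20) {
    B <- runif(1, 0.05, 0.95)
    p <- list(B = B, q = 0, tau = 0.01,
              x1_low = runif(1, 0.10, 0.40), x1_high = 0.03)
    sim <- simulate_sequence(p, rep("LOW", 30), noise = "none")
    gap <- sim$fc_est - 0.09
    above <- which(gap > 1e-9)
    above <- above[above < nrow(sim)]
    expect_equal(gap[above + 1], gap[above] * (1 - B), tolerance = 1e-12)
  }
})
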