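# Independent oracles and shared small-scale fixtures. The oracles are
# written as naive scalar code on purpose: they check the package's
# implementations without sharing any of their code paths.

# Naive per-trial reference loop for the dual-context state-space model.
reference_simulate <- function(B, q, x1_low, x1_high, height_class,
                               h_lower, h_upper, variant = "dot") {
  xl <- x1_low
  xh <- x1_high
  n <- length(height_class)
  fc <- err <- numeric(n)
  for (t in seq_len(n)) {
    low <- height_class[t] == "LOW"
    cl <- if (low) 1 else q
    ch <- if (low) q else 1
    fc[t] <- if (variant == "select") {
      if (low) xl else xh
    } else {
      xl * cl + xh * ch
    }
    e <- if (fc[t] > h_upper[t]) {
      h_upper[t] - fc[t]
    } else if (fc[t] < h_lower[t]) {
      h_lower[t] - fc[t]
    } else 0
    xl <- xl + B * e * cl
    xh <- xh + B * e * ch
    err[t] <- e
  }
  list(fc_est = fc, error = err, x_low = xl, x_high = xh)
}

# Brute-force trim-and-count probability of direction: sort, drop the outer
# 2.5% count on each side, count signs.
pd_oracle <- function(x, level = 0.95) {
  x <- sort(x)
  n <- length(x)
  drop <- floor(n * (1 - level) / 2)
  keep <- x[(drop + 1):(n - drop)]
  n_neg <- sum(keep < 0)
  n_pos <- sum(keep > 0)
  max(n_neg, n_pos) / (n_neg + n_pos)
}

# Reduced study design used by the slower estimation tests.
small_design <- function(...) {
  cohort_design(n_control = 6, n_pd = 6, n_bouts = 2, bout_size = 32,
                no_feedback_bout = 2, n_baseline_per_height = 12,
                n_retention_per_height = 8, ...)
}

quick_fit <- function(trials, ...) {
  loco_fit(trials, chains = 2, iter = 1500, burn_in = 800, thin = 2,
           seed = 42, ...)
}

# Lazily computed design-scale cohort + fit shared by the acceptance
# criteria 4 and 5 (one ~20 s MCMC run instead of two).
.acceptance_cache <- new.env(parent = emptyenv())
acceptance_recovery_fit <- function() {
  if (is.null(.acceptance_cache$fit)) {
    .acceptance_cache$cohort <- generate_cohort(seed = 1)
    .acceptance_cache$fit <- loco_fit(.acceptance_cache$cohort$trials,
                                      chains = 3, iter = 10000,
                                      burn_in = 6000, thin = 2, seed = 101)
  }
  list(cohort = .acceptance_cache$cohort, fit = .acceptance_cache$fit)
}
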