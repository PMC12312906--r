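# Population-level Bayesian hypothesis tests: probability of direction on
# (sigmoid-transformed) group differences, and ROPE tests on standardized
# effect sizes of the untransformed hyper-parameters.

#' Probability of direction of a posterior difference
#'
#' The difference draws are first trimmed to their central 95% equal-tailed
#' credible interval; the probability of direction is the larger of the
#' fractions of the retained draws above and below zero, reported in
#' `[0.5, 1]`. With contrasts computed as control minus PD, a negative
#' direction means the parameter is greater in the PD group.
#'
#' Trimming before counting follows the procedure this package mirrors; the
#' conventional definition (no trimming) is available with `trim = FALSE`.
#' An HDI-based trim is available as an alternative to the equal-tailed one.
#'
#' @param diff_draws Numeric vector of posterior difference draws (>= 100).
#' @param trim Trim to the central 95% before counting? Default TRUE.
#' @param level Credible level used for trimming.
#' @param interval `"eti"` (equal-tailed, default) or `"hdi"`.
#' @return List with `pd` (in `[0.5, 1]`), `direction` (`"positive"` /
#'   `"negative"`), `p_negative`, `p_positive`, `n_used`.
#' @export
probability_of_direction <- function(diff_draws, trim = TRUE, level = 0.95,
                                     interval = c("eti", "hdi")) {
  interval <- match.arg(interval)
  if (length(diff_draws) < 100) stop("need at least 100 draws")
  if (any(!is.finite(diff_draws))) stop("draws must be finite")
  if (all(diff_draws == 0))
    stop("all draws are exactly zero: direction undefined")
  x <- diff_draws
  if (trim) {
    bounds <- if (interval == "eti") {
      quantile(x, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
    } else {
      hdi_interval(x, level)
    }
    x <- x[x >= bounds[1] & x <= bounds[2]]
  }
  p_neg <- mean(x < 0)
  p_pos <- mean(x > 0)
  # draws exactly at zero count toward neither sign; renormalize
  tot <- p_neg + p_pos
  if (tot == 0) stop("all retained draws are zero: direction undefined")
  p_neg <- p_neg / tot; p_pos <- p_pos / tot
  list(pd = max(p_neg, p_pos),
       direction = if (p_neg >= p_pos) "negative" else "positive",
       p_negative = p_neg, p_positive = p_pos, n_used = length(x))
}

# Internal: shortest interval containing `level` of the draws.
hdi_interval <- function(x, level = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- max(1, floor(level * n))
  widths <- x[(m + 1):n] - x[seq_len(n - m)]
  i <- which.min(widths)
  c(x[i], x[i + m])
}

#' Standardized effect-size draws for a group contrast
#'
#' Elementwise `(theta_A - theta_B) / sqrt((sigma_A^2 + sigma_B^2) / 2)` on
#' the untransformed (logit) scale.
#'
#' @param theta_a,sigma_a,theta_b,sigma_b Aligned posterior draw vectors of
#'   the location and spread hyper-parameters for the two groups.
#' @return Numeric vector of effect-size draws.
#' @export
effect_size_draws <- function(theta_a, sigma_a, theta_b, sigma_b) {
  n <- length(theta_a)
  if (length(sigma_a) != n || length(theta_b) != n || length(sigma_b) != n)
    stop("draw vectors must have equal length")
  if (any(sigma_a <= 0) || any(sigma_b <= 0))
    stop("sigma draws must be positive")
  (theta_a - theta_b) / sqrt((sigma_a^2 + sigma_b^2) / 2)
}

#' ROPE test on effect-size draws
#'
#' Computes the posterior probability that the standardized effect lies
#' outside the region of practical equivalence (default `[-0.1, 0.1]`).
#' Verdict: `"meaningful"` if at least 95% of the mass is outside the ROPE,
#' `"negligible"` if at least 95% is inside, `"inconclusive"` otherwise.
#'
#' @param es_draws Numeric vector of effect-size draws.
#' @param rope Length-2 interval, default `c(-0.1, 0.1)`.
#' @param level Decision threshold, default 0.95.
#' @return List with `p_outside`, `p_inside`, `verdict`, `rope`.
#' @export
rope_test <- function(es_draws, rope = c(-0.1, 0.1), level = 0.95) {
  if (length(rope) != 2 || rope[1] >= rope[2])
    stop("rope must be an interval with lower < upper")
  if (any(!is.finite(es_draws))) stop("draws must be finite")
  outside <- mean(es_draws < rope[1] | es_draws > rope[2])
  verdict <- if (outside >= level) "meaningful"
             else if (1 - outside >= level) "negligible"
             else "inconclusive"
  list(p_outside = outside, p_inside = 1 - outside, verdict = verdict,
       rope = rope)
}

#' Group contrast of population learning parameters from a fit
#'
#' Builds the two population-level contrasts reported for this task:
#' the difference of sigmoid-transformed group locations (control minus PD
#' when both are present; otherwise first minus second group level) with its
#' probability of direction, and the standardized effect size of the
#' untransformed locations with its ROPE test.
#'
#' @param fit A `loco_fit` with two groups.
#' @param parameter `"learning_rate"` (theta_B) or `"interference"`
#'   (theta_q).
#' @param rope ROPE interval for the effect size.
#' @param trim Passed to [probability_of_direction()].
#' @return List with `parameter`, `groups` (A minus B order), `pd`,
#'   `direction`, `diff_summary` (median and 95% CI of the transformed
#'   difference), `rope` result, and the raw `diff_draws` / `es_draws`.
#' @export
group_contrast <- function(fit, parameter = c("learning_rate",
                                              "interference"),
                           rope = c(-0.1, 0.1), trim = TRUE) {
  parameter <- match.arg(parameter)
  stopifnot(inherits(fit, "loco_fit"))
  if (length(fit$group_levels) != 2)
    stop("group_contrast requires exactly 2 groups")
  stub <- if (parameter == "learning_rate") "B" else "q"
  g <- fit$group_levels
  m <- posterior_matrix(fit, c(paste0("theta_", stub, "[", g, "]"),
                               paste0("sigma_", stub, "[", g, "]")))
  diff_draws <- plogis(m[, 1]) - plogis(m[, 2])
  es <- effect_size_draws(m[, 1], m[, 3], m[, 2], m[, 4])
  pd <- probability_of_direction(diff_draws, trim = trim)
  list(parameter = parameter, groups = g,
       pd = pd$pd, direction = pd$direction,
       diff_summary = c(median = median(diff_draws),
                        lower = quantile(diff_draws, 0.025, names = FALSE),
                        upper = quantile(diff_draws, 0.975, names = FALSE)),
       rope = rope_test(es, rope),
       diff_draws = diff_draws, es_draws = es)
}
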