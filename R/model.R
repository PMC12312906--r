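#' Dead-zone trial error
#'
#' The error signal driving learning is zero when the (estimated) foot
#' clearance lies inside the closed success range `[h_lower, h_upper]`, and
#' otherwise equals the signed distance to the violated threshold. Negative
#' errors mean "reduce clearance on the next same-height obstacle".
#'
#' @param fc_est Estimated foot clearance (meters); may be a vector.
#' @param spec An [obstacle_spec()] row (or anything with `h_lower`,
#'   `h_upper`).
#' @return Signed error in meters, same length as `fc_est`.
#' @examples
#' lo <- obstacle_spec("LOW", 0.05, 0.05, 0.09)
#' compute_error(0.12, lo)  # -0.03: too high, come down
#' compute_error(0.07, lo)  # 0: inside the success range
#' compute_error(0.03, lo)  # +0.02: too low, go up
#' @export
compute_error <- function(fc_est, spec) {
  if (!is.numeric(fc_est) || any(!is.finite(fc_est)))
    stop("fc_est must be finite numeric")
  ifelse(fc_est > spec$h_upper, spec$h_upper - fc_est,
         ifelse(fc_est < spec$h_lower, spec$h_lower - fc_est, 0))
}

#' Context weights routing an update across the two height states
#'
#' Returns the weight pair `c = (c_low, c_high)`: `(1, q)` on LOW obstacles
#' and `(q, 1)` on HIGH obstacles. The first component always multiplies the
#' LOW state. `q` in `[0, 1]` is the interference parameter; `q = 1` is full
#' interference (both states receive the whole update).
#'
#' @param height_class `"LOW"` or `"HIGH"`.
#' @param q Interference in `[0, 1]`.
#' @return Numeric length-2 vector `(c_low, c_high)`.
#' @export
context_vector <- function(height_class, q) {
  height_class <- match.arg(height_class, HEIGHT_CLASSES)
  stopifnot(is.numeric(q), length(q) == 1, q >= 0, q <= 1)
  if (height_class == "LOW") c(1, q) else c(q, 1)
}

#' Motor output of the dual-context state-space model
#'
#' Two readings of how the two-component state maps to a single estimated
#' foot clearance:
#' \describe{
#'   \item{`"dot"`}{the literal inner product `x . c` of the state with the
#'     context vector (on a LOW trial, `x_low + q * x_high`);}
#'   \item{`"select"`}{the state component matching the current height class,
#'     ignoring the other one.}
#' }
#' `"dot"` is the default. Fits and simulations record which variant was
#' used.
#'
#' @param x_low,x_high State components (meters).
#' @param height_class `"LOW"` or `"HIGH"`.
#' @param q Interference in `[0, 1]`.
#' @param variant `"dot"` or `"select"`.
#' @return Estimated foot clearance (meters).
#' @export
motor_output <- function(x_low, x_high, height_class, q,
                         variant = c("dot", "select")) {
  variant <- match.arg(variant)
  height_class <- match.arg(height_class, HEIGHT_CLASSES)
  stopifnot(is.finite(x_low), is.finite(x_high))
  if (variant == "select")
    return(if (height_class == "LOW") x_low else x_high)
  cv <- context_vector(height_class, q)
  x_low * cv[1] + x_high * cv[2]
}

#' One learning update of the dual-context state
#'
#' `x' = x + B * e * c`, with `c = context_vector(height_class, q)`. A zero
#' error leaves the state exactly unchanged (the dead zone is absorbing
#' within a trial).
#'
#' @param x_low,x_high Current state (meters).
#' @param error Signed trial error (meters), from [compute_error()].
#' @param height_class `"LOW"` or `"HIGH"`.
#' @param B Learning rate in `[0, 1]`.
#' @param q Interference in `[0, 1]`.
#' @return Numeric length-2 vector: updated `(x_low, x_high)`.
#' @export
state_update <- function(x_low, x_high, error, height_class, B, q) {
  stopifnot(is.finite(error), is.numeric(B), B >= 0, B <= 1)
  cv <- context_vector(height_class, q)
  c(x_low + B * error * cv[1], x_high + B * error * cv[2])
}

#' Simulate a trial sequence through the state-space model
#'
#' Iterates motor output -> dead-zone error -> state update over a schedule
#' of obstacles. The error driving each update is computed from the model's
#' noiseless output `fc_est`; observation noise (if enabled) only perturbs
#' the recorded clearance `fc_obs = fc_est + tau * t_nu`.
#'
#' @param params A list/one-row data.frame with `B`, `q`, `tau`, `x1_low`,
#'   `x1_high` (and optionally `nu`, used when `noise = "student_t"`).
#' @param schedule Character vector of height classes (`"LOW"`/`"HIGH"`), or
#'   a data.frame with a `height_class` column.
#' @param specs Obstacle definitions, default [default_obstacle_specs()].
#' @param noise `"none"` or `"student_t"`.
#' @param nu Student-t degrees of freedom for the noise (default
#'   `params$nu`, else 5).
#' @param seed Optional integer seed; the simulation is reproducible given
#'   the seed.
#' @param variant Motor-output variant, see [motor_output()].
#' @return A `data.frame` with one row per trial: `trial`, `height_class`,
#'   `fc_est`, `fc_obs`, `error`, `x_low`, `x_high` (states *after* the
#'   trial's update).
#' @examples
#' p <- list(B = 0.1, q = 0, tau = 0.01, x1_low = 0.20, x1_high = 0.10)
#' sim <- simulate_sequence(p, rep("LOW", 10), noise = "none")
#' sim$fc_est[10]  # 0.09 + 0.11 * 0.9^9
#' @export
simulate_sequence <- function(params, schedule,
                              specs = default_obstacle_specs(),
                              noise = c("none", "student_t"),
                              nu = NULL, seed = NULL,
                              variant = c("dot", "select")) {
  noise <- match.arg(noise)
  variant <- match.arg(variant)
  if (is.data.frame(schedule)) schedule <- schedule$height_class
  if (length(schedule) == 0) stop("schedule must be non-empty")
  if (!all(schedule %in% HEIGHT_CLASSES))
    stop("schedule contains unknown height classes")
  check_specs(specs)
  stopifnot(params$B >= 0, params$B <= 1, params$q >= 0, params$q <= 1)

  sp <- spec_for_class(specs, schedule)
  h <- as.integer(schedule == "HIGH")  # 0 = LOW, 1 = HIGH
  res <- forward_sim_cpp(h, sp$h_lower, sp$h_upper,
                         params$B, params$q,
                         params$x1_low, params$x1_high,
                         variant == "select", rep(TRUE, length(h)))
  fc_obs <- res$fc_est
  if (noise == "student_t") {
    nu <- nu %||% params$nu %||% 5
    stopifnot(nu > 0, params$tau > 0)
    if (!is.null(seed)) set.seed(seed)
    fc_obs <- res$fc_est + params$tau * stats::rt(length(h), df = nu)
  }
  data.frame(trial = seq_along(h), height_class = schedule,
             fc_est = res$fc_est, fc_obs = fc_obs, error = res$error,
             x_low = res$x_low, x_high = res$x_high,
             stringsAsFactors = FALSE)
}
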