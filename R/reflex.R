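#' Effector mapping
#'
#' Describes how an action signal changes the controlled state:
#' `dx/dt = f(a) / lambda`, with `f` a deterministic mapping (identity by
#' default) and `lambda` the time constant of the effector pathway —
#' slow for hormonal regulation, fast for e.g. the baroreceptor reflex.
#'
#' @param transform A [transforms] object (or function), the mapping `f`.
#' @param time_constant Strictly positive time constant `lambda`, in
#'   simulation seconds per unit action effect.
#' @return An object of class `effector_map`.
#' @export
effector_map <- function(transform = identity_transform(), time_constant = 1) {
  transform <- as_transform(transform)
  if (!is.numeric(time_constant) || length(time_constant) != 1L ||
      !is.finite(time_constant) || time_constant <= 0)
    stop("time_constant must be a single finite, strictly positive number")
  structure(list(transform = transform, time_constant = time_constant),
            class = "effector_map")
}

#' @export
print.effector_map <- function(x, ...) {
  cat(sprintf("<effector_map: f = %s, time_constant = %g>\n",
              x$transform$name, x$time_constant))
  invisible(x)
}

#' Body state
#'
#' The controlled physiological variable and the simulation clock.
#'
#' @param value Current value of the physiological variable (finite).
#' @param time Simulation time in seconds, non-negative.
#' @return An object of class `body_state`.
#' @export
body_state <- function(value, time = 0) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
    stop("state value must be a single finite number")
  if (!is.numeric(time) || length(time) != 1L || !is.finite(time) || time < 0)
    stop("time must be a single finite, non-negative number")
  structure(list(value = value, time = time), class = "body_state")
}

#' Environmental perturbation
#'
#' Disturbances injected additively into the body state (not into the
#' sensory channel; sensor-level disturbances are modelled as lesions).
#' A `"step"` perturbation displaces the state once at onset by
#' `magnitude`; an `"impulse"` applies a constant forcing of `magnitude`
#' state-units per second throughout `[onset, onset + duration)`, so
#' sustained disturbances are composed from impulses.
#'
#' @param onset Non-negative onset time.
#' @param magnitude Displacement (step, state units) or forcing rate
#'   (impulse, state units per second).
#' @param kind `"step"` or `"impulse"`.
#' @param duration Duration of an impulse (ignored for steps).
#' @return An object of class `perturbation`.
#' @export
perturbation <- function(onset, magnitude, kind = c("step", "impulse"),
                         duration = 0) {
  kind <- match.arg(kind)
  if (!is.numeric(onset) || length(onset) != 1L || !is.finite(onset) ||
      onset < 0)
    stop("perturbation onset must be a single finite, non-negative number")
  if (!is.numeric(magnitude) || length(magnitude) != 1L ||
      !is.finite(magnitude))
    stop("perturbation magnitude must be a single finite number")
  if (!is.numeric(duration) || length(duration) != 1L ||
      !is.finite(duration) || duration < 0)
    stop("perturbation duration must be a single finite, non-negative number")
  structure(list(onset = onset, magnitude = magnitude, kind = kind,
                 duration = duration), class = "perturbation")
}

#' Action as the surprise gradient
#'
#' The reflex's action signal is the gradient of the log evidence of the
#' homeostasis-expecting model with respect to the controlled state:
#' \deqn{a = \partial L / \partial x
#'         = -\pi_{prior}\,(y - g(\mu_{prior}))\,\partial g/\partial x.}
#' Action vigor therefore scales with both the prediction error and the
#' precision of the setpoint belief: tight homeostatic ranges produce
#' rapid corrections.
#'
#' @param y Sensory input.
#' @param setpoint A [setpoint_belief()].
#' @param transform Coding transform `g` (default identity).
#' @param x State value at which to evaluate `dg/dx`. Required when the
#'   gradient of `g` is non-constant (the simulator passes the true state);
#'   ignored for transforms with constant gradient. An error is raised at
#'   points where the gradient vanishes, since the state-to-input mapping
#'   is not invertible there.
#' @return The action signal (single number).
#' @examples
#' sp <- setpoint_belief(1, 4)
#' action_signal(2.5, sp)  # -6
#' @export
action_signal <- function(y, setpoint, transform = identity_transform(),
                          x = NULL) {
  stopifnot(inherits(setpoint, "setpoint_belief"))
  transform <- as_transform(transform)
  if (!is.numeric(y) || length(y) != 1L || !is.finite(y))
    stop("y must be a single finite number")
  if (transform$name %in% c("identity", "linear")) {
    grad <- transform$grad(0)
  } else {
    if (is.null(x))
      stop("x is required to evaluate the gradient of a non-affine transform")
    grad <- transform_grad(transform, x, require_invertible = TRUE)
  }
  pe <- y - transform$fun(setpoint$mean)
  -setpoint$precision * pe * grad
}

#' Advance the controlled state by one Euler step
#'
#' Integrates `dx/dt = f(a) / lambda` with explicit Euler over `dt` and
#' injects the contribution of any perturbation active in
#' `[time, time + dt)`: steps displace the state once at onset, impulses
#' add `magnitude * dt`.
#'
#' @param state A [body_state()].
#' @param action Action signal `a` (single finite number).
#' @param effector An [effector_map()].
#' @param dt Strictly positive step size; must satisfy the Euler stability
#'   bound `dt < lambda / pi_prior` of the closed loop (checked by the
#'   simulation runner, which also guards against divergence).
#' @param perturbations List of [perturbation()] objects (may be empty).
#' @return The advanced [body_state()].
#' @export
step_state <- function(state, action, effector, dt, perturbations = list()) {
  stopifnot(inherits(state, "body_state"), inherits(effector, "effector_map"))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a single finite, strictly positive number")
  if (!is.numeric(action) || length(action) != 1L || !is.finite(action))
    stop("action must be a single finite number")
  if (inherits(perturbations, "perturbation"))
    perturbations <- list(perturbations)
  x <- state$value + dt * effector$transform$fun(action) /
    effector$time_constant
  t0 <- state$time
  t1 <- t0 + dt
  for (p in perturbations) {
    if (p$kind == "step") {
      if (p$onset >= t0 && p$onset < t1) x <- x + p$magnitude
    } else {
      overlap <- min(t1, p$onset + p$duration) - max(t0, p$onset)
      if (overlap > 0) x <- x + p$magnitude * overlap
    }
  }
  if (!is.finite(x) || abs(x) > 1e6)
    stop(sprintf(paste0("state diverged (|x| > 1e6) at t = %g; the ",
                        "dt/lambda/precision combination (dt = %g, ",
                        "lambda = %g) is unstable"),
                 t1, dt, effector$time_constant))
  body_state(x, t1)
}

#' Sense the body state through a noisy channel
#'
#' Draws a viscerosensory sample `y = g(x) + e` with `e` zero-mean Gaussian
#' with the map's generative `noise_sd` (exact `g(x)` when `noise_sd = 0`).
#' Uses R's global random number generator, so results are deterministic
#' after `set.seed()`.
#'
#' @param state A [body_state()] or a plain numeric state value.
#' @param map A [sensory_map()].
#' @param n Number of samples to draw (default 1).
#' @return Numeric vector of sensory samples.
#' @export
sense <- function(state, map, n = 1L) {
  stopifnot(inherits(map, "sensory_map"))
  x <- if (inherits(state, "body_state")) state$value else state
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("state value must be a single finite number")
  gx <- map$transform$fun(x)
  if (map$noise_sd == 0) return(rep(gx, n))
  gx + stats::rnorm(n, 0, map$noise_sd)
}
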