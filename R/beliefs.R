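#' Gaussian beliefs over a physiological state
#'
#' A setpoint belief is the Gaussian prior that defines a homeostatic
#' setpoint: its mean is the expected value of the physiological variable
#' and its precision (inverse variance) encodes the homeostatic range —
#' tight ranges for vitally important variables, wide ranges for tolerant
#' ones. A perceptual belief has the same sufficient statistics but is
#' updated sequentially from sensory samples ("today's posterior is
#' tomorrow's prior").
#'
#' @param mean Belief mean, in units of the physiological variable.
#' @param precision Belief precision (inverse squared units); must be
#'   strictly positive and finite.
#' @return An object of class `setpoint_belief` / `perceptual_belief`,
#'   a list with elements `mean` and `precision`.
#' @examples
#' setpoint_belief(mean = 1, precision = 1)
#' @export
setpoint_belief <- function(mean, precision) {
  check_belief(mean, precision)
  structure(list(mean = mean, precision = precision),
            class = c("setpoint_belief", "reflex_belief"))
}

#' @rdname setpoint_belief
#' @export
perceptual_belief <- function(mean, precision) {
  check_belief(mean, precision)
  structure(list(mean = mean, precision = precision),
            class = c("perceptual_belief", "reflex_belief"))
}

check_belief <- function(mean, precision) {
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean))
    stop("belief mean must be a single finite number")
  if (!is.numeric(precision) || length(precision) != 1L ||
      !is.finite(precision) || precision <= 0)
    stop("belief precision must be a single finite, strictly positive number")
  invisible(TRUE)
}

#' @export
print.reflex_belief <- function(x, ...) {
  cat(sprintf("<%s: mean = %g, precision = %g>\n", class(x)[1L],
              x$mean, x$precision))
  invisible(x)
}

#' Viscerosensory mapping
#'
#' Describes how the bodily state is turned into a sensory input: a coding
#' transform `g` plus channel noise. Two noise-related quantities are kept
#' deliberately separate: `data_precision` is the precision the *perceiver*
#' assigns to the channel when updating beliefs (zero means "ignore sensory
#' information", which clamps the belief), while `noise_sd` is the standard
#' deviation of the noise the *generative* channel actually injects when
#' simulating (see [sense()]).
#'
#' @param transform A [transforms] object (or plain function), the coding
#'   function `g`. Default identity.
#' @param data_precision Non-negative precision assigned to the sensory
#'   channel for belief updating.
#' @param noise_sd Non-negative standard deviation of simulated sensory
#'   noise. `0` gives noise-free sensing.
#' @return An object of class `sensory_map`.
#' @export
sensory_map <- function(transform = identity_transform(),
                        data_precision = 1, noise_sd = 0) {
  transform <- as_transform(transform)
  if (!is.numeric(data_precision) || length(data_precision) != 1L ||
      !is.finite(data_precision) || data_precision < 0)
    stop("data_precision must be a single finite, non-negative number")
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L ||
      !is.finite(noise_sd) || noise_sd < 0)
    stop("noise_sd must be a single finite, non-negative number")
  structure(list(transform = transform, data_precision = data_precision,
                 noise_sd = noise_sd),
            class = "sensory_map")
}

#' @export
print.sensory_map <- function(x, ...) {
  cat(sprintf("<sensory_map: g = %s, data_precision = %g, noise_sd = %g>\n",
              x$transform$name, x$data_precision, x$noise_sd))
  invisible(x)
}

#' Sequential precision-weighted belief update
#'
#' One step of conjugate Gaussian belief updating from a sensory sample:
#' the posterior mean is the prior mean corrected by the precision-weighted
#' prediction error and the posterior precision is the sum of prior and
#' data precision,
#' \deqn{\mu_{t+1} = \mu_t + \frac{\pi_{data}}{\pi_t + \pi_{data}}
#'       (y_t - g(\mu_t)), \qquad \pi_{t+1} = \pi_t + \pi_{data}.}
#' With `data_precision = 0` the belief is returned unchanged — ignoring
#' the sensory channel is exactly how a setpoint prior is clamped.
#'
#' @param belief A [perceptual_belief()] (or setpoint belief).
#' @param y Observed sensory input (single finite number).
#' @param map A [sensory_map()] supplying `g` and the data precision.
#' @return The updated belief, same class as the input.
#' @examples
#' b <- perceptual_belief(0, 1)
#' update_belief(b, y = 4, sensory_map(data_precision = 3))  # mean 3, precision 4
#' @export
update_belief <- function(belief, y, map) {
  stopifnot(inherits(belief, "reflex_belief"), inherits(map, "sensory_map"))
  if (!is.numeric(y) || length(y) != 1L || !is.finite(y))
    stop("y must be a single finite number")
  pd <- map$data_precision
  if (pd == 0) return(belief)
  pe <- y - map$transform$fun(belief$mean)
  belief$mean <- belief$mean + pd / (belief$precision + pd) * pe
  belief$precision <- belief$precision + pd
  belief
}

#' Log evidence and surprise under expected homeostasis
#'
#' The log evidence of the model that expects the body to be at its
#' homeostatic setpoint is the Gaussian log density of the sensory input
#' under the clamped setpoint belief:
#' \deqn{L = \tfrac12\left(\ln\pi_{prior} -
#'       \pi_{prior}\,(y - g(\mu_{prior}))^2\right) - \tfrac12\ln 2\pi.}
#' Interoceptive surprise is its negation, \eqn{S = -L}; it is minimal
#' exactly when the input equals its setpoint prediction, and chronically
#' elevated surprise is the formal signature of dyshomeostasis.
#' The additive constant is fixed to \eqn{-\frac12\ln 2\pi} so that `L` is
#' the exact normal log density (and `exp(-S)` integrates to one); all
#' model dynamics depend only on surprise differences, so this convention
#' is inert for behaviour.
#'
#' @param y Sensory input (single finite number; vectors are accepted and
#'   evaluated elementwise).
#' @param setpoint A [setpoint_belief()].
#' @param transform The coding transform `g` (default identity).
#' @return `log_evidence_homeostasis()`: the log evidence in nats.
#'   `interoceptive_surprise()`: the surprise in nats. `pwpe_squared()`:
#'   the squared precision-weighted prediction error
#'   \eqn{\pi_{prior}(y - g(\mu_{prior}))^2}, the quadratic term of `L`
#'   and the quantity plotted as the surprise approximation in simulation
#'   output.
#' @examples
#' sp <- setpoint_belief(1, 1)
#' log_evidence_homeostasis(1, sp)   # -0.5 * log(2 * pi)
#' interoceptive_surprise(2.5, sp) - interoceptive_surprise(1, sp)  # 1.125
#' pwpe_squared(2.5, sp)             # 2.25
#' @export
log_evidence_homeostasis <- function(y, setpoint,
                                     transform = identity_transform()) {
  stopifnot(inherits(setpoint, "setpoint_belief"))
  transform <- as_transform(transform)
  if (!is.numeric(y) || length(y) < 1L || any(!is.finite(y)))
    stop("y must be finite")
  pe <- y - transform$fun(setpoint$mean)
  0.5 * (log(setpoint$precision) - setpoint$precision * pe^2) -
    0.5 * log(2 * pi)
}

#' @rdname log_evidence_homeostasis
#' @export
interoceptive_surprise <- function(y, setpoint,
                                   transform = identity_transform()) {
  -log_evidence_homeostasis(y, setpoint, transform)
}

#' @rdname log_evidence_homeostasis
#' @export
pwpe_squared <- function(y, setpoint, transform = identity_transform()) {
  stopifnot(inherits(setpoint, "setpoint_belief"))
  transform <- as_transform(transform)
  if (!is.numeric(y) || length(y) < 1L || any(!is.finite(y)))
    stop("y must be finite")
  setpoint$precision * (y - transform$fun(setpoint$mean))^2
}

#' Surprise record
#'
#' Bundles the evidence-related quantities evaluated for one sensory
#' sample: log evidence, surprise, raw prediction error and squared
#' precision-weighted prediction error.
#'
#' @inheritParams log_evidence_homeostasis
#' @return A list of class `surprise_record` with elements `log_evidence`,
#'   `surprise`, `prediction_error`, `pwpe_sq`.
#' @export
surprise_record <- function(y, setpoint, transform = identity_transform()) {
  transform <- as_transform(transform)
  le <- log_evidence_homeostasis(y, setpoint, transform)
  structure(list(
    log_evidence = le,
    surprise = -le,
    prediction_error = y - transform$fun(setpoint$mean),
    pwpe_sq = pwpe_squared(y, setpoint, transform)
  ), class = "surprise_record")
}
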