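#' Allostatic events and schedules
#'
#' Allostasis — anticipatory "stability through change" — is modelled as
#' scheduled rewrites of the setpoint belief: a higher-level prediction
#' temporarily shifts the prior mean (a new setpoint) and/or its precision
#' (a tighter or looser homeostatic range). The generative model that
#' would produce such predictions is not modelled; schedules are inputs.
#'
#' @param time Non-negative event time.
#' @param new_mean Optional new prior mean (NULL to leave unchanged).
#' @param new_precision Optional new prior precision (> 0, NULL to leave
#'   unchanged). At least one of the two must be given.
#' @return `allostatic_event()`: an object of class `allostatic_event`.
#' @examples
#' sched <- allostatic_schedule(
#'   baseline = setpoint_belief(1, 1),
#'   events = list(allostatic_event(30, new_mean = 2),
#'                 allostatic_event(60, new_mean = 1),
#'                 allostatic_event(75, new_precision = 4)))
#' apply_allostatic_schedule(74, sched)  # mean 1, precision 1
#' apply_allostatic_schedule(75, sched)  # mean 1, precision 4
#' @export
allostatic_event <- function(time, new_mean = NULL, new_precision = NULL) {
  if (!is.numeric(time) || length(time) != 1L || !is.finite(time) || time < 0)
    stop("event time must be a single finite, non-negative number")
  if (is.null(new_mean) && is.null(new_precision))
    stop("an allostatic event must set at least one of new_mean/new_precision")
  if (!is.null(new_mean) &&
      (!is.numeric(new_mean) || length(new_mean) != 1L || !is.finite(new_mean)))
    stop("new_mean must be a single finite number")
  if (!is.null(new_precision) &&
      (!is.numeric(new_precision) || length(new_precision) != 1L ||
       !is.finite(new_precision) || new_precision <= 0))
    stop("new_precision must be a single finite, strictly positive number")
  structure(list(time = time, new_mean = new_mean,
                 new_precision = new_precision),
            class = "allostatic_event")
}

#' @rdname allostatic_event
#' @param baseline The baseline [setpoint_belief()] holding before any
#'   event.
#' @param events List of [allostatic_event()]s with strictly increasing
#'   times.
#' @export
allostatic_schedule <- function(baseline, events = list()) {
  stopifnot(inherits(baseline, "setpoint_belief"))
  if (inherits(events, "allostatic_event")) events <- list(events)
  for (e in events)
    if (!inherits(e, "allostatic_event"))
      stop("events must be allostatic_event objects")
  times <- vapply(events, `[[`, numeric(1), "time")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("allostatic event times must be strictly increasing")
  structure(list(baseline = baseline, events = events),
            class = "allostatic_schedule")
}

#' @export
print.allostatic_schedule <- function(x, ...) {
  cat(sprintf("<allostatic_schedule: baseline (mean %g, precision %g), %d event(s)>\n",
              x$baseline$mean, x$baseline$precision, length(x$events)))
  invisible(x)
}

#' Evaluate the setpoint belief at a time point
#'
#' Applies, in order, every event with `event.time <= t` to the baseline
#' belief; fields not set by an event persist from the most recent
#' applicable value. The resulting belief is piecewise constant in time
#' with closed-left semantics (an event holds from exactly its own time
#' onward).
#'
#' @param t Query time, non-negative.
#' @param schedule An [allostatic_schedule()].
#' @return The effective [setpoint_belief()] at time `t`.
#' @export
apply_allostatic_schedule <- function(t, schedule) {
  stopifnot(inherits(schedule, "allostatic_schedule"))
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0)
    stop("t must be a single finite, non-negative number")
  mean <- schedule$baseline$mean
  precision <- schedule$baseline$precision
  for (e in schedule$events) {
    if (e$time > t) break
    if (!is.null(e$new_mean)) mean <- e$new_mean
    if (!is.null(e$new_precision)) precision <- e$new_precision
  }
  setpoint_belief(mean, precision)
}

# piecewise-constant prior mean/precision on a time grid (vectorized form
# used by the simulation runner)
schedule_on_grid <- function(times, schedule) {
  mu <- rep(schedule$baseline$mean, length(times))
  prec <- rep(schedule$baseline$precision, length(times))
  for (e in schedule$events) {
    sel <- times >= e$time
    if (!is.null(e$new_mean)) mu[sel] <- e$new_mean
    if (!is.null(e$new_precision)) prec[sel] <- e$new_precision
  }
  list(mean = mu, precision = prec)
}

# maximal prior precision over a schedule (sets the Euler stability bound)
schedule_max_precision <- function(schedule) {
  precs <- c(schedule$baseline$precision,
             unlist(lapply(schedule$events, function(e) e$new_precision)))
  max(precs)
}
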