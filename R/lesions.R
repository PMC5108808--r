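#' Lesion specification
#'
#' A lesion injects one of five dysfunction origins into a scenario, each
#' the minimal one-or-two-parameter distortion of the corresponding
#' circuit component, active from `onset` for `duration` seconds
#' (permanent by default — the concern is chronic dyshomeostasis):
#'
#' * `sensor` — the viscerosensory channel reports `gain * g(x) + bias`
#'   while the controller's prediction `g(mu_prior)` is unchanged; a pure
#'   bias creates the "illusion" of dyshomeostasis (persistent prediction
#'   error with the body actually at setpoint). Params: `bias` (default
#'   0.75), `gain` (default 1).
#' * `predictor` — flawed allostatic predictions. Params: `mean_offset`
#'   added to every scheduled setpoint mean (default 0), `time_offset`
#'   added to event times (default 0), and `precision_scale` multiplying
#'   the prior precision globally (default 4) — the precision-pathway
#'   (monoaminergic) variant, which distorts the precision ratio weighting
#'   every prediction error.
#' * `effector` — actions are attenuated: the state change is
#'   `gain * f(a)` with `gain` in `[0, 1]` (default 0, a fully failed
#'   reflex arm).
#' * `body` — a disease process in the body itself: constant drift of
#'   `drift` state-units per second added to the dynamics (default 0.5),
#'   which an intact reflex can only balance at a standing bias of
#'   `drift * lambda / pi_prior`.
#' * `metacognition` — the self-efficacy prior is pinned low and
#'   (near-)rigid at onset: mean `pinned_mean` (default 0.1) with
#'   precision `pinned_precision` (default 100), so subsequent evidence
#'   barely moves it; dysregulation becomes the consequence, not the
#'   cause, of the low-self-efficacy belief.
#'
#' @param locus One of `"sensor"`, `"predictor"`, `"effector"`, `"body"`,
#'   `"metacognition"`.
#' @param onset Non-negative lesion onset time (default 0).
#' @param duration Lesion duration in seconds (default `Inf`, permanent).
#' @param params Named list of locus-specific parameters overriding the
#'   defaults above.
#' @return An object of class `lesion_spec`.
#' @examples
#' lesion_spec("effector", params = list(gain = 0))
#' @export
lesion_spec <- function(locus, onset = 0, duration = Inf, params = list()) {
  loci <- c("sensor", "predictor", "effector", "body", "metacognition")
  if (!is.character(locus) || length(locus) != 1L || !(locus %in% loci))
    stop("unknown lesion locus; must be one of: ",
         paste(loci, collapse = ", "))
  if (!is.numeric(onset) || length(onset) != 1L || !is.finite(onset) ||
      onset < 0)
    stop("lesion onset must be a single finite, non-negative number")
  if (!is.numeric(duration) || length(duration) != 1L || is.na(duration) ||
      duration <= 0)
    stop("lesion duration must be a single positive number (Inf allowed)")
  defaults <- switch(locus,
    sensor = list(bias = 0.75, gain = 1),
    predictor = list(mean_offset = 0, time_offset = 0, precision_scale = 4),
    effector = list(gain = 0),
    body = list(drift = 0.5),
    metacognition = list(pinned_mean = 0.1, pinned_precision = 100))
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop("unknown parameter(s) for ", locus, " lesion: ",
         paste(unknown, collapse = ", "))
  params <- utils::modifyList(defaults, params)
  if (locus == "effector" &&
      (params$gain < 0 || params$gain > 1))
    stop("effector lesion gain must lie in [0, 1]")
  if (locus == "predictor" && params$precision_scale <= 0)
    stop("predictor precision_scale must be strictly positive")
  if (locus == "metacognition" &&
      (params$pinned_mean < 0 || params$pinned_mean > 1 ||
       params$pinned_precision <= 0))
    stop("metacognition lesion needs pinned_mean in [0, 1] and positive pinned_precision")
  structure(list(locus = locus, onset = onset, duration = duration,
                 params = params),
            class = "lesion_spec")
}

#' @export
print.lesion_spec <- function(x, ...) {
  ps <- paste(names(x$params), unlist(x$params), sep = " = ", collapse = ", ")
  cat(sprintf("<lesion: %s from t = %g (duration %g); %s>\n",
              x$locus, x$onset, x$duration, ps))
  invisible(x)
}

#' Inject a lesion into a scenario
#'
#' Returns a copy of the scenario configuration carrying the lesion; the
#' distortions described in [lesion_spec()] are applied by
#' [run_simulation()] from the lesion's onset onward. An "identity"
#' lesion (neutral parameters) reproduces the unlesioned trajectories
#' exactly.
#'
#' @param config A [scenario_config()].
#' @param lesion A [lesion_spec()] (or `NULL` to remove one).
#' @return The modified [scenario_config()].
#' @export
apply_lesion <- function(config, lesion) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(lesion) && !inherits(lesion, "lesion_spec"))
    stop("lesion must be a lesion_spec (or NULL)")
  config$lesion <- lesion
  config
}

# schedule as seen through a predictor lesion (the lesion is assumed
# established before the events it distorts; event-time shifts keep the
# required strict ordering or error out at run time)
distort_schedule <- function(schedule, lesion) {
  if (is.null(lesion) || lesion$locus != "predictor") return(schedule)
  p <- lesion$params
  base <- schedule$baseline
  baseline <- setpoint_belief(base$mean + p$mean_offset,
                              base$precision * p$precision_scale)
  events <- lapply(schedule$events, function(e) {
    allostatic_event(
      time = e$time + p$time_offset,
      new_mean = if (is.null(e$new_mean)) NULL else e$new_mean + p$mean_offset,
      new_precision = if (is.null(e$new_precision)) NULL else
        e$new_precision * p$precision_scale)
  })
  allostatic_schedule(baseline, events)
}
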