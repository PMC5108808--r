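#' Metacognition parameters
#'
#' The metacognitive layer cannot see the hidden bodily state; it only
#' observes the circuit's surprise stream and its action output. At a
#' fixed cadence it inspects a trailing window: if actions are being
#' emitted but surprise is not falling, homeostatic control is failing,
#' and that verdict is folded as success/failure evidence into a Gaussian
#' belief over allostatic self-efficacy (the agent's confidence that it
#' can regulate its bodily states). Chronic low self-efficacy is then
#' staged: sustained crossing of a first threshold is labelled `fatigue`,
#' much longer crossing of a deeper threshold `generalized` (the
#' learned-helplessness-like, depression-prone stage).
#'
#' The self-efficacy belief is updated by the same precision-weighted rule
#' as perception ([update_belief()]), with the observation precision given
#' here; its precision is capped at `precision_cap` so that the belief
#' remains plastic under a long evidence stream. The slope tolerance is
#' relative to the window-mean surprise, so staging is invariant under
#' positive rescaling of the surprise series.
#'
#' @param window Length (seconds) of the monitored trailing window.
#' @param eval_every Cadence (seconds) of metacognitive evaluations.
#' @param action_threshold_frac "Acting" means max |a| in the window
#'   exceeds this fraction of the current prior precision.
#' @param slope_tol_frac Slope tolerance epsilon is this fraction of the
#'   absolute window-mean surprise per window length.
#' @param obs_precision Precision of one success/failure observation.
#' @param se_prior_mean,se_prior_precision Initial self-efficacy belief
#'   (mean on the 0-1 success scale).
#' @param precision_cap Upper bound on the self-efficacy belief precision.
#' @param theta_fatigue,theta_gen Stage thresholds on the self-efficacy
#'   mean; must satisfy `theta_gen <= theta_fatigue`.
#' @param d_fatigue,d_gen,d_recover Dwell times (seconds): how long
#'   self-efficacy must stay below `theta_fatigue` (resp. `theta_gen`) to
#'   enter `fatigue` (resp. `generalized`), and above `theta_fatigue` to
#'   step back toward `normal`. Defaults are 10x, 50x and 10x the window.
#' @return An object of class `metacog_config`.
#' @export
metacog_config <- function(window = 5, eval_every = 1,
                           action_threshold_frac = 0.01,
                           slope_tol_frac = 0.01,
                           obs_precision = 1,
                           se_prior_mean = 0.9, se_prior_precision = 5,
                           precision_cap = 10,
                           theta_fatigue = 0.5, theta_gen = 0.25,
                           d_fatigue = 10 * window, d_gen = 50 * window,
                           d_recover = 10 * window) {
  stopifnot(window > 0, eval_every > 0, action_threshold_frac >= 0,
            slope_tol_frac >= 0, obs_precision > 0,
            se_prior_mean >= 0, se_prior_mean <= 1, se_prior_precision > 0,
            precision_cap >= se_prior_precision,
            d_fatigue > 0, d_gen > 0, d_recover > 0)
  if (!(theta_gen <= theta_fatigue))
    stop("stage thresholds must be ordered: theta_gen <= theta_fatigue")
  structure(list(window = window, eval_every = eval_every,
                 action_threshold_frac = action_threshold_frac,
                 slope_tol_frac = slope_tol_frac,
                 obs_precision = obs_precision,
                 se_prior_mean = se_prior_mean,
                 se_prior_precision = se_prior_precision,
                 precision_cap = precision_cap,
                 theta_fatigue = theta_fatigue, theta_gen = theta_gen,
                 d_fatigue = d_fatigue, d_gen = d_gen,
                 d_recover = d_recover),
            class = "metacog_config")
}

#' Metacognitive state
#'
#' The self-efficacy belief (a [perceptual_belief()] over control success
#' on the 0-1 scale), the monitored window length, and the current stage.
#'
#' @param self_efficacy A [perceptual_belief()] with mean in `[0, 1]`.
#' @param window Monitored window length (seconds).
#' @param stage One of `"normal"`, `"fatigue"`, `"generalized"`.
#' @return An object of class `metacog_state`.
#' @export
metacog_state <- function(self_efficacy = perceptual_belief(0.9, 5),
                          window = 5,
                          stage = c("normal", "fatigue", "generalized")) {
  stage <- match.arg(stage)
  stopifnot(inherits(self_efficacy, "reflex_belief"),
            self_efficacy$mean >= 0, self_efficacy$mean <= 1, window > 0)
  structure(list(self_efficacy = self_efficacy, window = window,
                 stage = stage),
            class = "metacog_state")
}

#' @export
print.metacog_state <- function(x, ...) {
  cat(sprintf("<metacog_state: self-efficacy %.3f (precision %.2f), stage %s>\n",
              x$self_efficacy$mean, x$self_efficacy$precision, x$stage))
  invisible(x)
}

#' Monitor a trajectory window
#'
#' Summarizes a trailing window of the surprise and action streams:
#' the ordinary-least-squares slope of surprise against time (the
#' observable correlate of a failing or succeeding descent on surprise),
#' the window-mean surprise, the free action (trapezoidal time integral of
#' surprise over the window, the windowed proxy for accumulated negative
#' log evidence), and whether the circuit was acting (max |a| above
#' `action_threshold`).
#'
#' @param times Sample times (non-decreasing, length >= 2).
#' @param surprise Surprise values at `times` (nats).
#' @param actions Action signal values at `times`.
#' @param window Window length in seconds (metadata; carried into the
#'   report for threshold scaling).
#' @param action_threshold Absolute action threshold defining "acting".
#' @return An object of class `monitor_report` with elements
#'   `surprise_slope`, `mean_surprise`, `free_action`, `acting`, `window`.
#' @examples
#' t <- seq(0, 10, by = 0.5)
#' monitor(t, rep(2, length(t)), rep(1, length(t)), window = 10)
#' @export
monitor <- function(times, surprise, actions, window,
                    action_threshold = 0.01) {
  if (length(times) < 2L)
    stop("monitor window must contain at least 2 samples")
  stopifnot(length(surprise) == length(times),
            length(actions) == length(times),
            all(is.finite(times)), all(is.finite(surprise)),
            all(is.finite(actions)), window > 0)
  tc <- times - mean(times)
  denom <- sum(tc^2)
  slope <- if (denom > 0) sum(tc * (surprise - mean(surprise))) / denom else 0
  dt <- diff(times)
  fa <- sum(dt * (surprise[-length(surprise)] + surprise[-1]) / 2)
  structure(list(surprise_slope = slope,
                 mean_surprise = mean(surprise),
                 free_action = fa,
                 acting = max(abs(actions)) > action_threshold,
                 window = window),
            class = "monitor_report")
}

# success/failure observation implied by a monitor report:
# 1 = acting and surprise falling, 0 = acting and surprise flat/rising,
# NA = not acting (no evidence about control efficacy)
control_observation <- function(report, slope_tol_frac = 0.01) {
  if (!report$acting) return(NA_real_)
  eps <- slope_tol_frac * abs(report$mean_surprise) / report$window
  as.numeric(report$surprise_slope < -eps)
}

#' Update the allostatic self-efficacy belief
#'
#' Turns a [monitor()] report into a control-success observation (success
#' if acting while surprise falls, failure if acting while surprise stays
#' flat or rises, no observation if not acting) and folds it into the
#' self-efficacy belief with the precision-weighted update rule. The
#' posterior mean is clamped to `[0, 1]` and the posterior precision is
#' capped so the belief stays responsive.
#'
#' @param state A [metacog_state()].
#' @param report A [monitor()] report.
#' @param config A [metacog_config()].
#' @return The updated [metacog_state()] (stage is not changed here; see
#'   [classify_stage()]).
#' @export
update_self_efficacy <- function(state, report, config = metacog_config()) {
  stopifnot(inherits(state, "metacog_state"),
            inherits(report, "monitor_report"),
            inherits(config, "metacog_config"))
  s <- control_observation(report, config$slope_tol_frac)
  if (is.na(s)) return(state)
  b <- state$self_efficacy
  k <- config$obs_precision / (b$precision + config$obs_precision)
  m <- min(1, max(0, b$mean + k * (s - b$mean)))
  p <- min(b$precision + config$obs_precision,
           max(config$precision_cap, b$precision))
  state$self_efficacy <- perceptual_belief(m, p)
  state
}

#' Stage the fatigue/generalized progression
#'
#' Classifies a self-efficacy history into the two-stage progression:
#' `fatigue` once the self-efficacy mean has stayed below `theta_fatigue`
#' for `d_fatigue` seconds, `generalized` once it has additionally stayed
#' below the deeper `theta_gen` for the longer `d_gen`, stepping back
#' toward `normal` (generalized -> fatigue -> normal) after recovery above
#' `theta_fatigue` for `d_recover`. Transitions only ever move one stage
#' at a time, so `generalized` is never entered before `fatigue`.
#'
#' @param times Sample times (strictly increasing).
#' @param self_efficacy Self-efficacy means at `times`.
#' @param config A [metacog_config()] supplying thresholds and dwell
#'   times.
#' @return Character vector of stages, one per sample.
#' @examples
#' cfg <- metacog_config(window = 1)
#' classify_stage(0:100, rep(0.9, 101), cfg)[101]  # "normal"
#' @export
classify_stage <- function(times, self_efficacy, config = metacog_config()) {
  stopifnot(inherits(config, "metacog_config"))
  n <- length(times)
  if (n < 1L) stop("self-efficacy history must be non-empty")
  stopifnot(length(self_efficacy) == n, all(is.finite(self_efficacy)))
  if (n > 1L && any(diff(times) <= 0))
    stop("history times must be strictly increasing")
  stage <- character(n)
  cur <- "normal"
  below_fat <- 0; below_gen <- 0; above_fat <- 0
  for (i in seq_len(n)) {
    dt <- if (i == 1L) 0 else times[i] - times[i - 1L]
    e <- self_efficacy[i]
    below_fat <- if (e < config$theta_fatigue) below_fat + dt else 0
    below_gen <- if (e < config$theta_gen) below_gen + dt else 0
    above_fat <- if (e > config$theta_fatigue) above_fat + dt else 0
    if (cur == "normal" && below_fat >= config$d_fatigue) {
      cur <- "fatigue"
    } else if (cur == "fatigue" && below_gen >= config$d_gen) {
      cur <- "generalized"
    } else if (cur != "normal" && above_fat >= config$d_recover) {
      cur <- if (cur == "generalized") "fatigue" else "normal"
      above_fat <- 0
    }
    stage[i] <- cur
  }
  stage
}
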