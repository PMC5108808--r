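#' Scenario configuration
#'
#' Bundles everything a simulation run needs: the baseline setpoint
#' belief, the sensory and effector mappings, integration settings, the
#' perturbation list, the allostatic schedule, an optional lesion, the
#' metacognition parameters and the random seed.
#'
#' @param baseline Baseline [setpoint_belief()].
#' @param sensory A [sensory_map()] (its `noise_sd` is the generative
#'   sensory noise).
#' @param effector An [effector_map()].
#' @param duration Total simulated time, strictly positive.
#' @param dt Integration step. `NULL` (default) chooses
#'   `0.01 * lambda / max(pi_prior)` over the whole schedule (lesions
#'   included), well inside the Euler stability bound
#'   `dt < lambda / pi_prior` of the linear closed loop.
#' @param perturbations List of [perturbation()] objects.
#' @param events List of [allostatic_event()] objects (strictly
#'   increasing times).
#' @param lesion Optional [lesion_spec()].
#' @param metacog A [metacog_config()].
#' @param seed Integer seed; mandatory so that every noisy trajectory is
#'   reproducible.
#' @param init_state Initial state value (default: the baseline mean).
#' @return An object of class `scenario_config`.
#' @seealso [run_simulation()], [figure6_preset()]
#' @export
scenario_config <- function(baseline = setpoint_belief(1, 1),
                            sensory = sensory_map(),
                            effector = effector_map(),
                            duration = 100,
                            dt = NULL,
                            perturbations = list(),
                            events = list(),
                            lesion = NULL,
                            metacog = metacog_config(),
                            seed = 1L,
                            init_state = NULL) {
  stopifnot(inherits(baseline, "setpoint_belief"),
            inherits(sensory, "sensory_map"),
            inherits(effector, "effector_map"),
            inherits(metacog, "metacog_config"))
  if (!is.numeric(duration) || length(duration) != 1L ||
      !is.finite(duration) || duration <= 0)
    stop("duration must be a single finite, strictly positive number")
  if (inherits(perturbations, "perturbation"))
    perturbations <- list(perturbations)
  for (p in perturbations)
    if (!inherits(p, "perturbation")) stop("perturbations must be perturbation objects")
  schedule <- allostatic_schedule(baseline, events)   # validates ordering
  if (!is.null(lesion) && !inherits(lesion, "lesion_spec"))
    stop("lesion must be a lesion_spec or NULL")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed) ||
      seed != round(seed))
    stop("seed must be a single integer")
  if (!is.null(init_state) &&
      (!is.numeric(init_state) || length(init_state) != 1L ||
       !is.finite(init_state)))
    stop("init_state must be a single finite number (or NULL)")
  cfg <- structure(list(baseline = baseline, sensory = sensory,
                        effector = effector, duration = duration, dt = dt,
                        perturbations = perturbations,
                        events = schedule$events, lesion = lesion,
                        metacog = metacog, seed = as.integer(seed),
                        init_state = init_state),
                   class = "scenario_config")
  resolve_dt(cfg)   # validates a user-supplied dt against stability
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(paste0("<scenario: duration %g, dt %g, baseline (mean %g, ",
                     "precision %g), %d perturbation(s), %d allostatic ",
                     "event(s), noise sd %g, lesion %s, seed %d>\n"),
              x$duration, resolve_dt(x), x$baseline$mean,
              x$baseline$precision, length(x$perturbations),
              length(x$events), x$sensory$noise_sd,
              if (is.null(x$lesion)) "none" else x$lesion$locus, x$seed))
  invisible(x)
}

scenario_schedule <- function(config) {
  allostatic_schedule(config$baseline, config$events)
}

# maximal prior precision the run can encounter, lesion included
scenario_max_precision <- function(config) {
  sched <- scenario_schedule(config)
  pmax_ <- schedule_max_precision(sched)
  if (!is.null(config$lesion) && config$lesion$locus == "predictor")
    pmax_ <- max(pmax_,
                 schedule_max_precision(distort_schedule(sched, config$lesion)))
  pmax_
}

resolve_dt <- function(config) {
  lam <- config$effector$time_constant
  pmax_ <- scenario_max_precision(config)
  if (is.null(config$dt)) return(0.01 * lam / pmax_)
  dt <- config$dt
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a single finite, strictly positive number")
  if (dt >= lam / pmax_)
    stop(sprintf(paste0("dt = %g violates the stability bound dt < ",
                        "lambda/pi_prior = %g (lambda = %g, max prior ",
                        "precision = %g)"), dt, lam / pmax_, lam, pmax_))
  dt
}

HALF_LOG_2PI <- 0.5 * log(2 * pi)

#' Run a scenario
#'
#' Integrates the reflex arc over the scenario's duration with explicit
#' Euler steps. Each step evaluates the allostatic schedule (the current
#' setpoint belief), senses the state through the noisy channel, computes
#' prediction error, surprise, squared precision-weighted prediction
#' error and the action signal, and advances the state under the effector
#' plus any active perturbations and lesion distortions. The metacognitive
#' layer is evaluated on a coarser cadence (see [metacog_config()]) and
#' its self-efficacy belief and stage label are carried into the output
#' as step functions.
#'
#' Runs are deterministic given the configuration seed; the seed is set at
#' entry and all sensory noise is drawn from it.
#'
#' @param config A [scenario_config()].
#' @return A data frame of class `reflex_trajectory` with one row per
#'   step and columns `time`, `x`, `y`, `pe`, `pwpe_sq`, `surprise`,
#'   `action`, `mu_prior`, `pi_prior`, `self_efficacy`, `stage`. The
#'   configuration is attached as attribute `config`.
#' @examples
#' traj <- run_simulation(scenario_config(duration = 5))
#' range(traj$x)   # stays at the setpoint: 1 1
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  dt <- resolve_dt(config)
  lam <- config$effector$time_constant
  n <- floor(config$duration / dt + 1e-9)
  if (n < 2L) stop("duration too short for the chosen dt")
  times <- (seq_len(n) - 1) * dt

  # setpoint belief on the grid, with predictor-lesion distortion while
  # the lesion is active
  sched <- scenario_schedule(config)
  grid <- schedule_on_grid(times, sched)
  lesion <- config$lesion
  lesion_active <- rep(FALSE, n)
  if (!is.null(lesion))
    lesion_active <- times >= lesion$onset &
      times < lesion$onset + lesion$duration
  if (!is.null(lesion) && lesion$locus == "predictor") {
    dgrid <- schedule_on_grid(times, distort_schedule(sched, lesion))
    grid$mean[lesion_active] <- dgrid$mean[lesion_active]
    grid$precision[lesion_active] <- dgrid$precision[lesion_active]
  }
  mu <- grid$mean
  prec <- grid$precision

  # lesion distortion vectors (neutral when inactive)
  sgain <- rep(1, n); sbias <- rep(0, n)
  egain <- rep(1, n); drift <- rep(0, n)
  if (!is.null(lesion)) {
    if (lesion$locus == "sensor") {
      sgain[lesion_active] <- lesion$params$gain
      sbias[lesion_active] <- lesion$params$bias
    } else if (lesion$locus == "effector") {
      egain[lesion_active] <- lesion$params$gain
    } else if (lesion$locus == "body") {
      drift[lesion_active] <- lesion$params$drift
    }
  }

  # per-step perturbation injections (applied while stepping from i to i+1)
  pert <- numeric(n)
  for (p in config$perturbations) {
    if (p$onset >= config$duration) next
    if (p$kind == "step") {
      i <- floor(p$onset / dt + 1e-9) + 1
      if (i <= n) pert[i] <- pert[i] + p$magnitude
    } else {
      i0 <- max(1L, floor(p$onset / dt + 1e-9) + 1L)
      i1 <- min(n, floor((p$onset + p$duration) / dt + 1e-9) + 1L)
      idx <- i0:i1
      lo <- pmax(times[idx], p$onset)
      hi <- pmin(times[idx] + dt, p$onset + p$duration)
      pert[idx] <- pert[idx] + p$magnitude * pmax(0, hi - lo)
    }
  }

  set.seed(config$seed)
  noise <- if (config$sensory$noise_sd > 0)
    stats::rnorm(n, 0, config$sensory$noise_sd) else numeric(n)

  gt <- config$sensory$transform
  gfun <- gt$fun
  g_affine <- gt$name %in% c("identity", "linear")
  gconst <- if (g_affine) gt$grad(0) else NA_real_
  ft <- config$effector$transform
  ffun <- ft$fun
  f_ident <- ft$name == "identity"
  gmu <- gfun(mu)

  x <- numeric(n); yv <- numeric(n); pev <- numeric(n); av <- numeric(n)
  xi <- if (is.null(config$init_state)) config$baseline$mean else
    config$init_state
  for (i in seq_len(n)) {
    x[i] <- xi
    y <- gfun(xi) * sgain[i] + sbias[i] + noise[i]
    pe <- y - gmu[i]
    grad <- if (g_affine) gconst else
      transform_grad(gt, xi, require_invertible = TRUE)
    a <- -prec[i] * pe * grad
    yv[i] <- y; pev[i] <- pe; av[i] <- a
    fa <- if (f_ident) a else ffun(a)
    xi <- xi + dt * (egain[i] * fa / lam + drift[i]) + pert[i]
    if (!is.finite(xi) || abs(xi) > 1e6)
      stop(sprintf(paste0("state diverged at step %d (t = %g): dt = %g, ",
                          "lambda = %g, prior precision = %g"),
                   i, times[i], dt, lam, prec[i]))
  }

  pwpe <- prec * pev^2
  surprise <- HALF_LOG_2PI - 0.5 * (log(prec) - pwpe)

  # metacognitive layer on its own cadence
  mc <- config$metacog
  te <- if (mc$window < times[n])
    seq(mc$window, times[n], by = mc$eval_every) else numeric(0)
  se_mean <- numeric(length(te))
  m <- mc$se_prior_mean; p <- mc$se_prior_precision
  pinned <- FALSE
  mstate <- metacog_state(perceptual_belief(m, p), mc$window)
  for (k in seq_along(te)) {
    if (!is.null(lesion) && lesion$locus == "metacognition" && !pinned &&
        te[k] >= lesion$onset && te[k] < lesion$onset + lesion$duration) {
      mstate$self_efficacy <- perceptual_belief(lesion$params$pinned_mean,
                                                lesion$params$pinned_precision)
      pinned <- TRUE
    }
    lo <- max(1L, floor((te[k] - mc$window) / dt + 1e-9) + 2L)
    hi <- min(n, floor(te[k] / dt + 1e-9) + 1L)
    if (hi - lo >= 1L) {
      pi_now <- prec[hi]
      rep_ <- monitor(times[lo:hi], surprise[lo:hi], av[lo:hi],
                      window = mc$window,
                      action_threshold = mc$action_threshold_frac * pi_now)
      mstate <- update_self_efficacy(mstate, rep_, mc)
    }
    se_mean[k] <- mstate$self_efficacy$mean
  }
  cls_t <- c(0, te)
  cls_e <- c(mc$se_prior_mean, se_mean)
  cls_stage <- classify_stage(cls_t, cls_e, mc)
  seg <- findInterval(times, te) + 1L   # 1 = before first evaluation
  se_step <- cls_e[seg]
  stage_step <- cls_stage[seg]

  out <- data.frame(time = times, x = x, y = yv, pe = pev, pwpe_sq = pwpe,
                    surprise = surprise, action = av, mu_prior = mu,
                    pi_prior = prec, self_efficacy = se_step,
                    stage = stage_step, stringsAsFactors = FALSE)
  attr(out, "config") <- config
  attr(out, "dt") <- dt
  class(out) <- c("reflex_trajectory", "data.frame")
  out
}

#' Reference allostatic-regulation scenario
#'
#' The preset used throughout this package's documentation and acceptance
#' checks: a unit setpoint belief (prior mean 1, prior precision 1),
#' sensory noise of standard deviation 0.25, identity sensory and effector
#' mappings with unit time constant, and six scheduled incidents —
#' three step perturbations of magnitude 1.5, an anticipatory setpoint
#' shift to 2, a reset back to 1 during a predicted safe period, and a
#' precision increase from 1 to 4 when a perturbation of uncertain
#' direction is predicted. Event times default to a uniform grid
#' (t = 15, 30, 45, 60, 75, 90 over a 120-second run); only the ordering
#' is meaningful and the times are freely configurable.
#'
#' @param noise_sd Sensory noise standard deviation (set 0 for the
#'   noise-free variant).
#' @param seed Random seed for the noisy variant.
#' @param event_times Increasing vector of the six incident times:
#'   perturbation, mean shift, perturbation, mean reset, precision
#'   increase, perturbation.
#' @param duration Total run length.
#' @return A [scenario_config()].
#' @examples
#' cfg <- figure6_preset(noise_sd = 0)
#' traj <- run_simulation(cfg)
#' @export
figure6_preset <- function(noise_sd = 0.25, seed = 42L,
                           event_times = c(15, 30, 45, 60, 75, 90),
                           duration = 120) {
  stopifnot(length(event_times) == 6L, all(diff(event_times) > 0),
            all(event_times > 0), max(event_times) < duration)
  scenario_config(
    baseline = setpoint_belief(1, 1),
    sensory = sensory_map(identity_transform(), data_precision = 0,
                          noise_sd = noise_sd),
    effector = effector_map(identity_transform(), time_constant = 1),
    duration = duration,
    perturbations = list(
      perturbation(event_times[1], 1.5, "step"),
      perturbation(event_times[3], 1.5, "step"),
      perturbation(event_times[6], 1.5, "step")),
    events = list(
      allostatic_event(event_times[2], new_mean = 2),
      allostatic_event(event_times[4], new_mean = 1),
      allostatic_event(event_times[5], new_precision = 4)),
    seed = seed)
}

#' Generate a synthetic perturbation schedule
#'
#' Draws `n` step perturbations with Gaussian magnitudes and Gaussian
#' inter-event spacings (degenerate at zero standard deviation). Onsets
#' are the cumulative sums of the spacings and are strictly increasing;
#' non-positive drawn spacings are rejected with an error.
#'
#' @param n Number of perturbations (0 gives an empty list).
#' @param mag_mean,mag_sd Magnitude distribution parameters.
#' @param spacing_mean,spacing_sd Inter-event-time distribution
#'   parameters (`spacing_mean > 0`).
#' @param kind Perturbation kind, `"step"` or `"impulse"`.
#' @param duration Duration of each impulse (ignored for steps).
#' @param seed Optional seed (`NULL`: use the current RNG state).
#' @return List of [perturbation()] objects.
#' @examples
#' generate_perturbation_schedule(3, spacing_mean = 10)  # onsets 10, 20, 30
#' @export
generate_perturbation_schedule <- function(n, mag_mean = 1.5, mag_sd = 0,
                                           spacing_mean = 10,
                                           spacing_sd = 0,
                                           kind = c("step", "impulse"),
                                           duration = 0, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n))
    stop("n must be a single non-negative integer")
  if (spacing_mean <= 0 || spacing_sd < 0 || mag_sd < 0)
    stop("invalid distribution parameters: spacing_mean must be positive, ",
         "standard deviations non-negative")
  if (n == 0) return(list())
  if (!is.null(seed)) set.seed(seed)
  spacings <- stats::rnorm(n, spacing_mean, spacing_sd)
  if (any(spacings <= 0))
    stop("drawn inter-event spacing was non-positive; reduce spacing_sd")
  onsets <- cumsum(spacings)
  mags <- stats::rnorm(n, mag_mean, mag_sd)
  lapply(seq_len(n), function(i)
    perturbation(onsets[i], mags[i], kind, duration))
}
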