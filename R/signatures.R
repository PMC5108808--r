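#' Shared scenario for comparing lesion classes
#'
#' An 80-second scenario used to profile the five lesion loci on an
#' identical footing: unit baseline belief, sensory noise sd 0.25, an
#' allostatic episode (setpoint to 2 at t = 10, reset at t = 25) that
#' exposes predictor dysfunction, and a step perturbation of magnitude
#' 1.5 at t = 35 that probes the reflex.
#'
#' @param seed Integer seed for the run.
#' @param noise_sd Sensory noise standard deviation.
#' @return A [scenario_config()].
#' @seealso [classify_lesions()]
#' @export
lesion_panel_config <- function(seed = 1L, noise_sd = 0.25) {
  scenario_config(
    baseline = setpoint_belief(1, 1),
    sensory = sensory_map(identity_transform(), data_precision = 0,
                          noise_sd = noise_sd),
    effector = effector_map(identity_transform(), time_constant = 1),
    duration = 80,
    perturbations = list(perturbation(35, 1.5, "step")),
    events = list(allostatic_event(10, new_mean = 2),
                  allostatic_event(25, new_mean = 1)),
    seed = seed)
}

#' Trajectory signature features
#'
#' Reduces a trajectory to the five-feature tuple used to tell lesion
#' classes apart:
#' `pe_ss` (mean |prediction error| over the final 10 seconds, the
#' steady-state dyshomeostasis), `mean_pwpe` (run-mean squared
#' precision-weighted prediction error), `slope_act` (least-squares slope
#' of surprise over the 5 seconds following the probing perturbation,
#' i.e. during corrective action), `tts` (time after the perturbation
#' until the state stays within 0.1 of the *unlesioned* scheduled
#' setpoint for a full second; capped at the remaining run length when
#' the setpoint is never reached), and `stage_num` (final metacognitive
#' stage coded 0 = normal, 1 = fatigue, 2 = generalized).
#'
#' @param trajectory A `reflex_trajectory` carrying its configuration
#'   attribute.
#' @param settle_tol,settle_hold Setpoint tolerance (state units) and
#'   required hold time (seconds) for `tts`.
#' @return Named numeric vector of the five features.
#' @export
trajectory_signature <- function(trajectory, settle_tol = 0.1,
                                 settle_hold = 1) {
  cfg <- attr(trajectory, "config")
  if (is.null(cfg))
    stop("trajectory must carry its scenario_config attribute")
  times <- trajectory$time
  dur <- cfg$duration
  onset <- if (length(cfg$perturbations))
    max(vapply(cfg$perturbations, `[[`, numeric(1), "onset")) else 0

  tail_sel <- times >= dur - 10
  pe_ss <- mean(abs(trajectory$pe[tail_sel]))
  mean_pwpe <- mean(trajectory$pwpe_sq)

  win <- times >= onset & times <= onset + 5
  tc <- times[win] - mean(times[win])
  s <- trajectory$surprise[win]
  slope_act <- sum(tc * (s - mean(s))) / sum(tc^2)

  mu_base <- schedule_on_grid(times, scenario_schedule(cfg))$mean
  dev_ok <- abs(trajectory$x - mu_base) < settle_tol & times >= onset
  dt <- attr(trajectory, "dt")
  if (is.null(dt)) dt <- stats::median(diff(times))
  hold_n <- max(1L, ceiling(settle_hold / dt))
  r <- rle(dev_ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  good <- which(r$values & r$lengths >= hold_n)
  tts <- if (length(good)) times[starts[good[1]]] - onset else dur - onset

  stage_num <- match(trajectory$stage[nrow(trajectory)],
                     c("normal", "fatigue", "generalized")) - 1
  c(pe_ss = pe_ss, mean_pwpe = mean_pwpe, slope_act = slope_act,
    tts = tts, stage_num = stage_num)
}

#' Nearest-centroid separability of the five lesion classes
#'
#' Runs the shared panel scenario under each lesion locus (with the
#' documented default lesion parameters) for `n_reps` seeded replicates,
#' reduces every run to its [trajectory_signature()], and classifies each
#' run by the nearest class centroid in z-scored feature space. With
#' intact separability the five dysfunction origins are recovered almost
#' perfectly from their trajectory signatures alone.
#'
#' @param n_reps Replicates per lesion class.
#' @param seed Base seed; replicate `r` of locus `l` runs with seed
#'   `seed + 1000 * l + r`.
#' @param loci Character vector of loci to include.
#' @return A list with elements `features` (data frame of signatures with
#'   a `locus` column), `predicted`, `accuracy`, and `centroids`.
#' @examples
#' \donttest{
#' res <- classify_lesions(n_reps = 3, seed = 7)
#' res$accuracy
#' }
#' @export
classify_lesions <- function(n_reps = 20, seed = 1L,
                             loci = c("sensor", "predictor", "effector",
                                      "body", "metacognition")) {
  feats <- list()
  truth <- character(0)
  for (l in seq_along(loci)) {
    for (r in seq_len(n_reps)) {
      cfg <- lesion_panel_config(seed = seed + 1000L * l + r)
      cfg <- apply_lesion(cfg, lesion_spec(loci[l]))
      feats[[length(feats) + 1L]] <- trajectory_signature(run_simulation(cfg))
      truth <- c(truth, loci[l])
    }
  }
  fm <- do.call(rbind, feats)
  mu <- colMeans(fm)
  sdev <- apply(fm, 2, stats::sd)
  sdev[sdev < 1e-12] <- 1
  z <- sweep(sweep(fm, 2, mu), 2, sdev, "/")
  centroids <- do.call(rbind, lapply(loci, function(l)
    colMeans(z[truth == l, , drop = FALSE])))
  rownames(centroids) <- loci
  d2 <- vapply(loci, function(l)
    rowSums(sweep(z, 2, centroids[l, ])^2), numeric(nrow(z)))
  predicted <- loci[max.col(-d2)]
  list(features = data.frame(locus = truth, fm, row.names = NULL),
       predicted = predicted,
       accuracy = mean(predicted == truth),
       centroids = centroids)
}
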