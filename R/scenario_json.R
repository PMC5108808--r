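#' Scenario JSON serialization
#'
#' Scenario configurations are serialized to a documented JSON schema
#' with all defaults written out explicitly, so a stored file fully
#' determines a run (the seed included). Transforms are stored by name
#' and parameters; custom function transforms cannot be serialized.
#'
#' @param config A [scenario_config()].
#' @param path File path.
#' @return `write_scenario()`: `path`, invisibly. `read_scenario()`: the
#'   reconstructed [scenario_config()].
#' @export
write_scenario <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  jsonlite::write_json(scenario_to_list(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  scenario_from_list(jsonlite::read_json(path, simplifyVector = FALSE))
}

transform_to_list <- function(tr) {
  if (tr$name == "custom")
    stop("custom function transforms cannot be serialized to JSON")
  c(list(name = tr$name), tr$params)
}

transform_from_list <- function(x) {
  ps <- x[setdiff(names(x), "name")]
  switch(x$name,
    identity = identity_transform(),
    linear = do.call(linear_transform, ps),
    logistic = do.call(logistic_transform, ps),
    saturating = do.call(saturating_transform, ps),
    stop("unknown transform name in scenario file: ", x$name))
}

scenario_to_list <- function(config) {
  list(
    baseline = list(mean = config$baseline$mean,
                    precision = config$baseline$precision),
    sensory = list(transform = transform_to_list(config$sensory$transform),
                   data_precision = config$sensory$data_precision,
                   noise_sd = config$sensory$noise_sd),
    effector = list(transform = transform_to_list(config$effector$transform),
                    time_constant = config$effector$time_constant),
    duration = config$duration,
    dt = config$dt,
    perturbations = lapply(config$perturbations, function(p)
      list(onset = p$onset, magnitude = p$magnitude, kind = p$kind,
           duration = p$duration)),
    events = lapply(config$events, function(e)
      list(time = e$time, new_mean = e$new_mean,
           new_precision = e$new_precision)),
    lesion = if (is.null(config$lesion)) NULL else
      list(locus = config$lesion$locus, onset = config$lesion$onset,
           duration = if (is.finite(config$lesion$duration))
             config$lesion$duration else "Inf",
           params = config$lesion$params),
    metacog = unclass(config$metacog),
    seed = config$seed,
    init_state = config$init_state)
}

num_or_null <- function(x) if (is.null(x)) NULL else as.numeric(x)

scenario_from_list <- function(x) {
  lesion <- NULL
  if (!is.null(x$lesion)) {
    dur <- x$lesion$duration
    dur <- if (identical(dur, "Inf")) Inf else as.numeric(dur)
    lesion <- lesion_spec(x$lesion$locus, onset = as.numeric(x$lesion$onset),
                          duration = dur,
                          params = lapply(x$lesion$params, as.numeric))
  }
  scenario_config(
    baseline = setpoint_belief(as.numeric(x$baseline$mean),
                               as.numeric(x$baseline$precision)),
    sensory = sensory_map(transform_from_list(x$sensory$transform),
                          data_precision = as.numeric(x$sensory$data_precision),
                          noise_sd = as.numeric(x$sensory$noise_sd)),
    effector = effector_map(transform_from_list(x$effector$transform),
                            time_constant = as.numeric(x$effector$time_constant)),
    duration = as.numeric(x$duration),
    dt = num_or_null(x$dt),
    perturbations = lapply(x$perturbations, function(p)
      perturbation(as.numeric(p$onset), as.numeric(p$magnitude), p$kind,
                   as.numeric(p$duration))),
    events = lapply(x$events, function(e)
      allostatic_event(as.numeric(e$time), num_or_null(e$new_mean),
                       num_or_null(e$new_precision))),
    lesion = lesion,
    metacog = do.call(metacog_config, lapply(x$metacog, as.numeric)),
    seed = as.integer(x$seed),
    init_state = num_or_null(x$init_state))
}
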