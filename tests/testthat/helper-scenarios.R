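# small scenario builders shared across test files

# noise-free relaxation from a displaced initial state (identity maps)
relaxation_config <- function(precision = 1, lambda = 1, x0 = 2.5,
                              mu = 1, dt = NULL, duration = 10) {
  scenario_config(
    baseline = setpoint_belief(mu, precision),
    sensory = sensory_map(identity_transform(), data_precision = 0,
                          noise_sd = 0),
    effector = effector_map(identity_transform(), time_constant = lambda),
    duration = duration, dt = dt, init_state = x0, seed = 1L)
}

# effector-lesioned run with one sustained (step) perturbation, used for
# staging checks; `lesion_duration` allows a healing lesion
staging_config <- function(duration = 400, lesion_duration = Inf,
                           lesioned = TRUE) {
  cfg <- scenario_config(
    baseline = setpoint_belief(1, 1),
    sensory = sensory_map(identity_transform(), data_precision = 0,
                          noise_sd = 0),
    effector = effector_map(identity_transform(), time_constant = 1),
    duration = duration, dt = 0.01,
    perturbations = list(perturbation(5, 1.5, "step")),
    seed = 7L)
  if (lesioned)
    cfg <- apply_lesion(cfg, lesion_spec("effector", onset = 0,
                                         duration = lesion_duration,
                                         params = list(gain = 0)))
  cfg
}

first_time_in_stage <- function(traj, stage) {
  idx <- which(traj$stage == stage)
  if (length(idx)) traj$time[idx[1]] else Inf
}
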