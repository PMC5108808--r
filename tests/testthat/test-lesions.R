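test_that("lesion specs validate their locus and parameters", {
  expect_error(lesion_spec("thalamus"), "unknown lesion locus")
  expect_error(lesion_spec("effector", params = list(gain = 1.5)), "\\[0, 1\\]")
  expect_error(lesion_spec("sensor", params = list(drift = 1)), "unknown parameter")
  l <- lesion_spec("body", params = list(drift = 0.2))
  expect_equal(l$params$drift, 0.2)
  expect_true(is.infinite(l$duration))
})

test_that("a sensor bias creates the illusion of dyshomeostasis", {
  # inert effector (f = 0) holds x at the setpoint; the biased channel
  # still reports a persistent prediction error and elevated surprise
  cfg <- scenario_config(
    baseline = setpoint_belief(1, 1),
    sensory = sensory_map(data_precision = 0, noise_sd = 0),
    effector = effector_map(linear_transform(0), time_constant = 1),
    duration = 10, dt = 0.005, seed = 1L,
    lesion = lesion_spec("sensor", params = list(bias = 0.5, gain = 1)))
  tr <- run_simulation(cfg)
  expect_true(all(tr$x == 1))                  # body truly at setpoint
  expect_true(all(abs(tr$pe - 0.5) < 1e-12))   # illusory PE persists
  smin <- interoceptive_surprise(1, setpoint_belief(1, 1))
  expect_true(all(tr$surprise > smin + 0.1))
})

test_that("a neutral lesion reproduces the unlesioned run bitwise", {
  base <- lesion_panel_config(seed = 5L)
  neutral <- apply_lesion(base, lesion_spec("sensor",
                                            params = list(bias = 0, gain = 1)))
  t1 <- run_simulation(base)
  t2 <- run_simulation(neutral)
  for (col in c("x", "y", "pe", "pwpe_sq", "surprise", "action",
                "self_efficacy"))
    expect_identical(t1[[col]], t2[[col]])
})

test_that("an effector lesion prevents convergence and drives fatigue", {
  tr <- run_simulation(staging_config(duration = 120))
  post <- tr$time > 5
  expect_true(all(abs(tr$x[post] - 1) > 1.4))          # never returns
  sel <- tr$time >= 20 & tr$time <= 30
  rep_ <- monitor(tr$time[sel], tr$surprise[sel], tr$action[sel], window = 10)
  expect_gte(rep_$surprise_slope, -1e-9)               # surprise not falling
  expect_true(rep_$acting)
  expect_true("fatigue" %in% tr$stage)
})

test_that("predictor lesions distort scheduled setpoints and precision weighting", {
  base <- lesion_panel_config(seed = 2L)
  off <- apply_lesion(base, lesion_spec(
    "predictor", params = list(mean_offset = 1, precision_scale = 1)))
  tro <- run_simulation(off)
  # during the allostatic episode the lesioned prior aims at 3, not 2
  expect_equal(unique(tro$mu_prior[tro$time >= 10 & tro$time < 25]), 3)
  expect_equal(unique(tro$mu_prior[tro$time >= 25]), 2)
  scaled <- apply_lesion(base, lesion_spec(
    "predictor", params = list(mean_offset = 0, precision_scale = 4)))
  trs <- run_simulation(scaled)
  expect_equal(unique(trs$pi_prior), 4)
})

test_that("body drift within capacity yields a bounded bias, beyond it divergence", {
  # intact linear reflex balances drift r at a standing bias r*lambda/pi
  cfg <- scenario_config(
    baseline = setpoint_belief(1, 2), sensory = sensory_map(data_precision = 0),
    effector = effector_map(time_constant = 1), duration = 30, dt = 0.005,
    seed = 1L, lesion = lesion_spec("body", params = list(drift = 0.5)))
  tr <- run_simulation(cfg)
  tail_x <- tr$x[tr$time > 20]
  expect_equal(mean(tail_x), 1 + 0.5 * 1 / 2, tolerance = 1e-6)
  expect_lt(diff(range(tail_x)), 1e-6)

  # a saturating effector has finite corrective capacity: drift faster
  # than the cap escapes regulation and surprise grows without bound
  cfg2 <- scenario_config(
    baseline = setpoint_belief(1, 2), sensory = sensory_map(data_precision = 0),
    effector = effector_map(saturating_transform(cap = 0.3),
                            time_constant = 1),
    duration = 60, dt = 0.005, seed = 1L,
    lesion = lesion_spec("body", params = list(drift = 0.5)))
  tr2 <- run_simulation(cfg2)
  late <- tr2$time > 10
  expect_true(all(diff(tr2$x[late]) > 0))              # runaway state
  s_t <- tr2$surprise[late]
  expect_gt(s_t[length(s_t)], 10 * s_t[1])             # unbounded surprise
})

test_that("a metacognitive lesion pins self-efficacy low without touching physiology", {
  base <- staging_config(duration = 120, lesioned = FALSE)
  les <- apply_lesion(base, lesion_spec("metacognition"))
  t1 <- run_simulation(base)
  t2 <- run_simulation(les)
  expect_identical(t1$x, t2$x)                         # body unaffected
  expect_true(all(t2$self_efficacy[t2$time > 10] < 0.15))
  expect_true("fatigue" %in% t2$stage)
  expect_true(all(t1$stage == "normal"))
})
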