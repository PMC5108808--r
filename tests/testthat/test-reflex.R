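test_that("action is the gradient of log evidence with respect to state", {
  sp <- setpoint_belief(1, 1)
  expect_equal(action_signal(1, sp), 0)
  expect_equal(action_signal(2.5, sp), -1.5)
  expect_equal(action_signal(2.5, setpoint_belief(1, 4)), -6)

  # finite-difference check of dL/dx through y = g(x), identity g
  for (prec in c(1, 4)) {
    spp <- setpoint_belief(1, prec)
    Lx <- function(x) log_evidence_homeostasis(x, spp)
    h <- 1e-6
    for (x in c(0.2, 1.7, 2.5)) {
      num <- (Lx(x + h) - Lx(x - h)) / (2 * h)
      expect_lt(abs(action_signal(x, spp) - num), 1e-6)
    }
  }

  # non-affine g: gradient evaluated at the true state, chain rule intact
  g <- logistic_transform(scale = 2, slope = 1, midpoint = 0)
  x <- 0.4
  y <- g$fun(x)
  a <- action_signal(y, sp, g, x = x)
  Lx <- function(x_) log_evidence_homeostasis(g$fun(x_), sp, g)
  num <- (Lx(x + 1e-6) - Lx(x - 1e-6)) / 2e-6
  expect_lt(abs(a - num), 1e-6)
  expect_error(action_signal(y, sp, g), "required")

  # non-invertible coding at a critical point is refused
  gsq <- as_transform(function(x) x^2)
  expect_error(action_signal(0.5, sp, gsq, x = 0), "vanishing|invertible")
})

test_that("step_state integrates the effector and injects perturbations", {
  eff <- effector_map(time_constant = 2)
  s0 <- body_state(1, 0)
  expect_equal(step_state(s0, 0, eff, 0.1)$value, 1)
  expect_equal(step_state(s0, 0.5, eff, 0.1)$value, 1 + 0.1 * 0.5 / 2)
  # step perturbation lands once, inside its own interval
  p <- perturbation(0.05, 1.5, "step")
  expect_equal(step_state(s0, 0, eff, 0.1, list(p))$value, 2.5)
  s1 <- body_state(1, 0.1)
  expect_equal(step_state(s1, 0, eff, 0.1, list(p))$value, 1)
  # impulse contributes rate * overlap
  pi_ <- perturbation(0, 2, "impulse", duration = 0.05)
  expect_equal(step_state(s0, 0, eff, 0.1, list(pi_))$value, 1 + 2 * 0.05)
  expect_error(step_state(s0, 0, eff, -0.1), "positive")
  expect_error(step_state(body_state(9e5), 1e12, effector_map(), 1),
               "diverged")
})

test_that("noise-free relaxation matches the closed-form exponential", {
  # dx/dt = -pi/lambda (x - mu)  =>  x(t) = mu + (x0 - mu) exp(-pi t/lambda)
  for (prec in c(1, 4)) {
    lam <- 1
    dt <- 1e-3 * lam / prec
    tr <- run_simulation(relaxation_config(precision = prec, lambda = lam,
                                           x0 = 2.5, dt = dt, duration = 5))
    exact <- 1 + 1.5 * exp(-prec * tr$time / lam)
    # pointwise over the first time constant
    early <- tr$time <= lam / prec
    expect_lt(max(abs(tr$x[early] - exact[early]) /
                    abs(exact[early] - 1)), 1e-3)
    # and relative to the initial displacement over the whole run
    expect_lt(max(abs(tr$x - exact)) / 1.5, 1e-3)
  }
})

test_that("action, prediction error and pwPE^2 co-vanish", {
  tr <- run_simulation(relaxation_config(x0 = 2.5, duration = 3))
  expect_identical(tr$action == 0, tr$pe == 0)
  expect_identical(tr$pwpe_sq == 0, tr$pe == 0)
  expect_true(all(abs(tr$action) > 0))  # still relaxing: all nonzero
  tr0 <- run_simulation(relaxation_config(x0 = 1, duration = 1))
  expect_true(all(tr0$action == 0 & tr0$pe == 0 & tr0$pwpe_sq == 0))
})

test_that("recovery from a step perturbation is monotone when noise-free", {
  cfg <- relaxation_config(x0 = 1, duration = 12)
  cfg$perturbations <- list(perturbation(2, 1.5, "step"))
  tr <- run_simulation(cfg)
  dev <- abs(tr$x - 1)
  post <- which(tr$time > 2 + attr(tr, "dt") & dev > 1e-9)
  expect_true(all(diff(dev[post]) < 0))
  # the jump itself has the perturbation's magnitude
  expect_equal(max(tr$x), 2.5, tolerance = 1e-9)
})

test_that("tighter priors drive proportionally faster correction", {
  # time to halve the deviation scales as 1/precision
  t_half <- sapply(c(1, 2, 4), function(prec) {
    tr <- run_simulation(relaxation_config(precision = prec, x0 = 2.5,
                                           dt = 0.001, duration = 4))
    tr$time[which(abs(tr$x - 1) < 0.75)[1]]
  })
  expect_equal(t_half[1] / t_half[2], 2, tolerance = 0.02)
  expect_equal(t_half[1] / t_half[3], 4, tolerance = 0.02)
  expect_equal(t_half, log(2) / c(1, 2, 4), tolerance = 0.02)
})

test_that("higher prior precision passes more sensory noise into the state", {
  var_x <- sapply(c(1, 4), function(prec) {
    cfg <- scenario_config(
      baseline = setpoint_belief(1, prec),
      sensory = sensory_map(noise_sd = 0.25, data_precision = 0),
      effector = effector_map(time_constant = 1),
      duration = 200, dt = 0.01, seed = 11L)
    tr <- run_simulation(cfg)
    var(tr$x[tr$time > 20])   # >= 10^4 stationary steps
  })
  expect_gt(var_x[2], 2 * var_x[1])
})

test_that("sense reproduces the configured noise level and is seed-deterministic", {
  m0 <- sensory_map(noise_sd = 0)
  expect_identical(sense(body_state(1), m0), 1)
  m <- sensory_map(noise_sd = 0.25)
  set.seed(5)
  y <- sense(body_state(0), m, n = 1e5)
  expect_lt(abs(sd(y) - 0.25) / 0.25, 0.01)
  expect_lt(abs(mean(y)), 0.005)
  set.seed(99); y1 <- sense(body_state(2), m, n = 50)
  set.seed(99); y2 <- sense(body_state(2), m, n = 50)
  expect_identical(y1, y2)
  expect_error(sensory_map(noise_sd = -1), "non-negative")
})
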