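test_that("a quiet scenario sits at the setpoint with minimal surprise", {
  tr <- run_simulation(scenario_config(duration = 5, seed = 1L))
  expect_true(all(tr$x == 1))
  expect_true(all(tr$action == 0))
  smin <- interoceptive_surprise(1, setpoint_belief(1, 1))
  expect_true(all(tr$surprise == smin))
  expect_true(all(tr$stage == "normal"))
})

test_that("runs are deterministic given config and seed", {
  cfg <- figure6_preset(seed = 123L)
  t1 <- run_simulation(cfg)
  t2 <- run_simulation(cfg)
  expect_identical(t1$x, t2$x)
  expect_identical(t1$y, t2$y)
  t3 <- run_simulation(figure6_preset(seed = 124L))
  expect_false(identical(t1$y, t3$y))
})

test_that("the reference preset encodes the documented study conditions", {
  cfg <- figure6_preset()
  expect_equal(cfg$baseline$mean, 1)
  expect_equal(cfg$baseline$precision, 1)
  expect_equal(cfg$sensory$noise_sd, 0.25)
  mags <- vapply(cfg$perturbations, `[[`, numeric(1), "magnitude")
  expect_equal(mags, c(1.5, 1.5, 1.5))
  expect_equal(cfg$events[[1]]$new_mean, 2)
  expect_equal(cfg$events[[2]]$new_mean, 1)
  expect_equal(cfg$events[[3]]$new_precision, 4)
  # the auto step respects the stability bound of the tightest prior era
  dt_used <- attr(run_simulation(figure6_preset(noise_sd = 0)), "dt")
  expect_equal(dt_used, 0.01 * 1 / 4)
})

test_that("synthetic perturbation schedules honour their distributions", {
  expect_identical(generate_perturbation_schedule(0), list())
  ps <- generate_perturbation_schedule(3, mag_mean = 1.5, mag_sd = 0,
                                       spacing_mean = 10, spacing_sd = 0)
  expect_equal(vapply(ps, `[[`, numeric(1), "onset"), c(10, 20, 30))
  expect_equal(vapply(ps, `[[`, numeric(1), "magnitude"), rep(1.5, 3))
  a <- generate_perturbation_schedule(5, mag_sd = 0.3, spacing_sd = 2,
                                      seed = 1)
  b <- generate_perturbation_schedule(5, mag_sd = 0.3, spacing_sd = 2,
                                      seed = 1)
  c_ <- generate_perturbation_schedule(5, mag_sd = 0.3, spacing_sd = 2,
                                       seed = 2)
  expect_identical(a, b)
  expect_false(identical(vapply(a, `[[`, numeric(1), "onset"),
                         vapply(c_, `[[`, numeric(1), "onset")))
  onsets <- vapply(c_, `[[`, numeric(1), "onset")
  expect_true(all(diff(onsets) > 0))
  expect_error(generate_perturbation_schedule(3, spacing_mean = -1),
               "invalid distribution")
})

test_that("trajectories round-trip through CSV and configs through JSON", {
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "run.csv")
  cfg <- figure6_preset(noise_sd = 0.25, duration = 10,
                        event_times = c(2, 3, 4, 5, 6, 7))
  tr <- run_simulation(cfg)
  write_trajectory(tr, csv)
  back <- read_trajectory(csv)
  expect_equal(nrow(back), nrow(tr))
  for (col in setdiff(names(tr), "stage"))
    expect_equal(back[[col]], tr[[col]], tolerance = 1e-12)
  expect_identical(back$stage, tr$stage)
  # the JSON sidecar reconstructs the full configuration, seed included
  cfg2 <- attr(back, "config")
  expect_equal(cfg2$seed, cfg$seed)
  expect_equal(cfg2$baseline, cfg$baseline)
  expect_equal(run_simulation(cfg2)$x, tr$x)

  # byte-identical output for identical config + seed
  csv2 <- file.path(dir, "run2.csv")
  write_trajectory(run_simulation(cfg), csv2, config_path = NA)
  expect_identical(readBin(csv, "raw", file.size(csv) + 10),
                   readBin(csv2, "raw", file.size(csv2) + 10)[
                     seq_len(file.size(csv2))])
  expect_identical(unname(tools::md5sum(csv))[1] == unname(tools::md5sum(csv2))[1],
                   TRUE)
})

test_that("trajectory reader reports schema and parse problems with line numbers", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.csv")
  writeLines(c("time,x,wrong", "0,1,2"), bad)
  expect_error(read_trajectory(bad), "line 1")
  hdr <- paste(c("time", "x", "y", "pe", "pwpe_sq", "surprise", "action",
                 "mu_prior", "pi_prior", "self_efficacy", "stage"),
               collapse = ",")
  bad2 <- file.path(dir, "bad2.csv")
  writeLines(c(hdr, "0,1,1,0,0,0.9,0,1,1,0.9,normal",
               "0.1,oops,1,0,0,0.9,0,1,1,0.9,normal"), bad2)
  expect_error(read_trajectory(bad2), "line 3")
  # header-only file reads back as an empty trajectory
  empty <- file.path(dir, "empty.csv")
  writeLines(hdr, empty)
  tre <- read_trajectory(empty)
  expect_equal(nrow(tre), 0)
  expect_identical(names(tre), strsplit(hdr, ",")[[1]])
})

test_that("unstable step sizes are refused with a diagnostic", {
  expect_error(
    scenario_config(baseline = setpoint_belief(1, 4), dt = 0.3,
                    duration = 10),
    "stability bound")
})
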