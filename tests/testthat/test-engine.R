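test_that("identical configs produce identical traces", {
  cfg <- simulation_config(target = fixture_short_target(),
                           weights = minimal_sc_weights(),
                           commands = command_set_from_vector(
                             c(0.4, 0.36, 0, 0.02, 0.3, 0.36, pi, 0.02)))
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$elbow_deg, b$elbow_deg)
  expect_identical(a$u, b$u)
})

test_that("compiled and pure-R engines agree to numerical precision", {
  cfg <- simulation_config(target = fixture_short_target(),
                           weights = synaptic_weights(
                             IaMN = 0.8, IaINa = 0.6, IaMNs = 0.5,
                             II = 0.4, Ib = 0.3, RN = 0.7),
                           commands = command_set_from_vector(
                             c(0.4, 0.36, 0, 0.02, 0.3, 0.36, pi, 0.02)),
                           perturbation = perturbation(10, "upward",
                                                       0.1, 0.03))
  a <- run_simulation(cfg, engine = "cpp")
  b <- run_simulation(cfg, engine = "r")
  expect_equal(a$elbow_deg, b$elbow_deg, tolerance = 1e-10)
  expect_equal(a$shoulder_deg, b$shoulder_deg, tolerance = 1e-10)
  expect_equal(a$u, b$u, tolerance = 1e-10)
  expect_equal(a$a, b$a, tolerance = 1e-10)
  expect_equal(a$force_n, b$force_n, tolerance = 1e-8)
  expect_equal(a$ia, b$ia, tolerance = 1e-10)
})

test_that("trace invariants hold: equal lengths and bounded signals", {
  cfg <- simulation_config(target = fixture_short_target(),
                           weights = minimal_sc_weights())
  tr <- run_simulation(cfg)
  n <- length(tr$time_s)
  expect_equal(length(tr$elbow_deg), n)
  expect_equal(nrow(tr$u), n)
  expect_true(all(tr$u >= 0 & tr$u <= 1))
  expect_true(all(tr$a >= 0 & tr$a <= 1))
  expect_true(all(tr$force_n >= 0))
  expect_equal(tr$elbow_deg[1], 20)
})

test_that("passive arm relaxes without blowing up", {
  cfg <- simulation_config(target = make_target())
  tr <- run_simulation(cfg)
  rom <- max(tr$elbow_deg) - min(tr$elbow_deg)
  expect_lt(rom, 15)          # sags modestly against passive tension
  expect_true(all(is.finite(tr$elbow_deg)))
})

test_that("loop is integration-convergent for the command-driven plant", {
  cmds <- command_set_from_vector(c(0.4, 0.36, 0, 0.02,
                                    0.3, 0.36, pi, 0.02))
  tgt <- make_target()
  a <- run_simulation(simulation_config(target = tgt, commands = cmds,
                                        dt_s = 0.001))
  b <- run_simulation(simulation_config(target = tgt, commands = cmds,
                                        dt_s = 0.0005))
  bb <- stats::approx(b$time_s, b$elbow_deg, a$time_s)$y
  expect_lt(sqrt(mean((a$elbow_deg - bb)^2)), 0.5)
})

test_that("perturbation impulse is dt-independent on the half-open window", {
  tgt <- fixture_short_target()
  pk <- function(dt) {
    cfg <- simulation_config(target = tgt, dt_s = dt,
                             perturbation = perturbation(30, "upward",
                                                         0.1, 0.03))
    tr <- run_simulation(cfg)
    max(abs(tr$elbow_speed_deg_s))
  }
  expect_equal(pk(0.001), pk(0.0005), tolerance = 0.03)
})

test_that("gravity environment set has the seven stated members", {
  envs <- gravity_environments()
  expect_length(envs, 7)
  key <- sapply(envs, function(e)
    paste(e$magnitude_scale, e$direction_rotation_deg))
  expect_true("2 0" %in% key)      # doubled gravity
  expect_true("1 -45" %in% key)    # the -45 deg rotation
  expect_true("1 90" %in% key)     # lying position
  expect_equal(sum(key == "1 0"), 1)  # exactly one normal gravity
  expect_setequal(sapply(envs, function(e) e$magnitude_scale)[1:4],
                  c(0.5, 1, 1.5, 2))
})

test_that("pathway sweep at weight zero equals the no-circuit baseline", {
  base <- simulation_config(target = fixture_short_target(),
                            commands = command_set_from_vector(
                              c(0.4, 0.36, 0, 0.02, 0.3, 0.36, pi, 0.02)))
  tab <- scenario_pathway_sweep("II", c(0, 0.5, 1), base)
  expect_equal(nrow(tab), 3)
  tr0 <- run_simulation(base)
  expect_equal(tab$rmse_deg[1], trajectory_rmse(tr0, base$target))
  expect_equal(tab$sal[1], elbow_sal(tr0))
  expect_error(scenario_pathway_sweep("II", c(0, 1.5), base), "weight")
})

test_that("perturbation scenario handles the null and scaling probes", {
  base <- simulation_config(target = fixture_short_target(),
                            commands = command_set_from_vector(
                              c(0.4, 0.36, 0, 0.02, 0.3, 0.36, pi, 0.02)))
  # zero-magnitude perturbation: deviation equals the unperturbed
  # post-onset excursion from the reference sample
  tab0 <- scenario_perturbation("IaMN", 0, base, force_magnitude_n = 0)
  cfg <- base; cfg$weights <- synaptic_weights(IaMN = 0)
  onset <- peak_flexion_time(cfg)
  tr <- run_simulation(cfg)
  expect_equal(tab0$deviation_deg[1], elbow_deviation(tr, onset))
  # larger force does not reduce the deviation
  devs <- sapply(c(10, 30, 60), function(f)
    scenario_perturbation("IaMN", 0.5, base,
                          force_magnitude_n = f)$deviation_deg)
  expect_true(all(diff(devs) >= -1e-6))
})
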