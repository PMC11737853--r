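# Shared fixtures, computed once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache))
    assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# Supraspinal commands optimised without any spinal circuit on the
# baseline flexion-extension target (the S1/S2 baseline drive). A modest
# budget keeps the test run fast; the optimum is deterministic (seed 1).
fixture_nosc_commands <- function() {
  cached("nosc_commands", {
    res <- optimise_supraspinal(make_target(), with_minimal_sc = FALSE,
                                budget_iterations = 60, seed = 1)
    res$best_commands
  })
}

fixture_base_config <- function() {
  simulation_config(target = make_target(),
                    commands = fixture_nosc_commands())
}

# Short target for fast closed-loop runs.
fixture_short_target <- function() {
  make_target(trajectory_spec(duration_s = 0.3, elbow_rom_deg = 40))
}

zero_forces <- function() {
  stats::setNames(rep(0, 7), muscle_names())
}
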