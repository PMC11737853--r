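#' Assemble a simulation configuration
#'
#' Bundles everything one closed-loop run needs: the target trajectory
#' (which fixes the initial posture and the default duration), the gravity
#' environment, the synaptic weight set, the supraspinal command set and an
#' optional hand perturbation. The integration step defaults to 1 ms,
#' matching the neuron time constant.
#'
#' @param target a `target_trajectory` (see [make_target()]).
#' @param weights a `synaptic_weights` matrix (default: all pathways off).
#' @param commands a `command_set` (default: no supraspinal drive).
#' @param gravity a `gravity_environment`.
#' @param perturbation optional list from [perturbation()].
#' @param dt_s integration step (s).
#' @param duration_s run length (s); defaults to the target duration.
#' @param arm,muscles,afferents,neuron parameter overrides.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(target = make_target(),
                              weights = synaptic_weights(),
                              commands = zero_command_set(),
                              gravity = gravity_environment(),
                              perturbation = NULL,
                              dt_s = 0.001,
                              duration_s = NULL,
                              arm = default_arm_parameters(),
                              muscles = default_muscle_parameters(),
                              afferents = default_afferent_parameters(),
                              neuron = default_neuron_parameters()) {
  if (is.null(duration_s))
    duration_s <- max(target$time_s)
  if (duration_s < max(target$time_s))
    stop("duration_s must be at least the target duration")
  steps <- afferents$delay_s / dt_s
  if (abs(steps - round(steps)) > 1e-9)
    stop("dt_s must divide the afferent delay")
  validate_arm_parameters(arm)
  validate_muscle_parameters(muscles)
  structure(list(target = target, weights = weights, commands = commands,
                 gravity = gravity, perturbation = perturbation,
                 dt_s = dt_s, duration_s = duration_s, arm = arm,
                 muscles = muscles, afferents = afferents,
                 neuron = neuron),
            class = "simulation_config")
}

#' Hand perturbation specification
#'
#' A world-frame force applied at the hand on the half-open window
#' `[onset, onset + duration)`, so the applied impulse is
#' `force * duration` regardless of the integration step.
#'
#' @param force_magnitude_n force magnitude (N); default 30.
#' @param direction "upward" (+y) or "downward" (-y).
#' @param onset_time_s onset (s).
#' @param duration_s application window (s), > 0; default 30 ms.
#' @return List of class `perturbation`.
#' @export
perturbation <- function(force_magnitude_n = 30,
                         direction = c("upward", "downward"),
                         onset_time_s = 0, duration_s = 0.030) {
  direction <- match.arg(direction)
  stopifnot(duration_s > 0, force_magnitude_n >= 0)
  structure(list(force_magnitude_n = force_magnitude_n,
                 direction = direction,
                 onset_time_s = onset_time_s,
                 duration_s = duration_s),
            class = "perturbation")
}

perturbation_force_vector <- function(p) {
  sgn <- if (p$direction == "upward") 1 else -1
  c(0, sgn * p$force_magnitude_n)
}

#' Run one closed-loop simulation
#'
#' Per step: (1) evaluate the supraspinal commands, (2) read the delayed
#' normalised afferent rates, (3) step the spinal network to get muscle
#' excitations, (4) step the activation dynamics, (5) compute muscle
#' geometry and Hill forces, (6) advance the arm dynamics under gravity and
#' any active perturbation, (7) push the new afferent samples into the
#' delay lines. Deterministic for a fixed config.
#'
#' @param config a `simulation_config`.
#' @param engine "cpp" (compiled, default) or "r" (pure-R reference route,
#'   identical arithmetic, used for cross-validation).
#' @return A `simulation_trace`: list with `time_s`, data.frame columns
#'   `shoulder_deg`, `elbow_deg`, `elbow_speed_deg_s`, and per-muscle
#'   matrices `u`, `a`, `force_n`, `ia`, `ii`, `ib`.
#' @export
run_simulation <- function(config, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(config, "simulation_config"))
  dt <- config$dt_s
  n_steps <- round(config$duration_s / dt)
  t_grid <- seq(0, by = dt, length.out = n_steps + 1)
  cmd <- command_matrix(config$commands, t_grid)
  q0 <- c(config$target$shoulder_deg[1],
          config$target$elbow_deg[1]) * pi / 180
  net <- build_network(config$weights)
  pert <- config$perturbation
  if (engine == "cpp") {
    mus <- config$muscles
    mus_list <- as.list(mus)
    mus_list$reference_posture_rad <-
      unname(attr(mus, "reference_posture_deg") * pi / 180)
    aff <- config$afferents
    aff$norm_ia_hz <- aff$normalisation_max_hz[["Ia"]]
    aff$norm_ii_hz <- aff$normalisation_max_hz[["II"]]
    aff$delay_steps <- as.integer(round(aff$delay_s / dt))
    res <- run_engine_cpp(
      n_steps, dt, q0, c(0, 0),
      config$arm, mus_list, aff, config$neuron, net, cmd,
      gravity_vector(config$gravity),
      !is.null(pert),
      if (is.null(pert)) c(0, 0) else perturbation_force_vector(pert),
      if (is.null(pert)) 0L else as.integer(round(pert$onset_time_s / dt)),
      if (is.null(pert)) 0L else
        as.integer(round((pert$onset_time_s + pert$duration_s) / dt))
    )
  } else {
    res <- run_engine_r(config, n_steps, dt, q0, cmd)
  }
  mn <- muscle_names()
  colnames(res$u) <- colnames(res$a) <- colnames(res$force) <- mn
  colnames(res$ia) <- colnames(res$ii) <- colnames(res$ib) <- mn
  structure(list(
    time_s = t_grid,
    shoulder_deg = res$theta[, 1] * 180 / pi,
    elbow_deg = res$theta[, 2] * 180 / pi,
    elbow_speed_deg_s = res$thetadot[, 2] * 180 / pi,
    u = res$u, a = res$a, force_n = res$force,
    ia = res$ia, ii = res$ii, ib = res$ib,
    config = config
  ), class = "simulation_trace")
}

# Pure-R closed loop built from the exported primitives; same arithmetic
# as the compiled engine, used to cross-validate it.
run_engine_r <- function(config, n_steps, dt, q0, cmd) {
  mus <- config$muscles
  aff <- config$afferents
  net <- build_network(config$weights)
  npar <- config$neuron
  state <- list(q = q0, qd = c(0, 0))
  a <- rep(0, 7)
  ns <- network_state_init(npar)
  pert <- config$perturbation
  i_on <- if (is.null(pert)) -1L else round(pert$onset_time_s / dt)
  i_off <- if (is.null(pert)) -1L else
    round((pert$onset_time_s + pert$duration_s) / dt)
  pf <- if (is.null(pert)) c(0, 0) else perturbation_force_vector(pert)

  rates_at <- function(st, act) {
    geo <- muscle_geometry(st$q[1], st$q[2], st$qd[1], st$qd[2], mus)
    f <- hill_force(act, geo$length_mm, geo$velocity_mm_s, mus)
    raw <- afferent_rates(geo$length_mm, geo$velocity_mm_s, f,
                          mus$optimal_fiber_length_mm, mus$f_max_n, aff)
    list(geo = geo, force = f,
         ia = normalise_rate(raw$ia_hz, "Ia", aff),
         ii = normalise_rate(raw$ii_hz, "II", aff),
         ib = normalise_rate(raw$ib, "Ib", aff))
  }
  r0 <- rates_at(state, a)
  dsteps <- round(aff$delay_s / dt)

  n_out <- n_steps + 1
  out <- list(theta = matrix(NA_real_, n_out, 2),
              thetadot = matrix(NA_real_, n_out, 2),
              u = matrix(NA_real_, n_out, 7), a = matrix(NA_real_, n_out, 7),
              force = matrix(NA_real_, n_out, 7),
              ia = matrix(NA_real_, n_out, 7),
              ii = matrix(NA_real_, n_out, 7),
              ib = matrix(NA_real_, n_out, 7))
  # afferent sample history, row i = sample generated at step i; a read at
  # step i returns row i - dsteps, or the pre-filled t = 0 sample earlier
  hist <- list(ia = matrix(NA_real_, n_steps, 7),
               ii = matrix(NA_real_, n_steps, 7),
               ib = matrix(NA_real_, n_steps, 7))
  delayed_sample <- function(type, i) {
    j <- i - dsteps
    if (j < 1) unname(unlist(r0[[type]])) else hist[[type]][j, ]
  }
  for (i in seq_len(n_steps)) {
    d_ia <- delayed_sample("ia", i)
    d_ii <- delayed_sample("ii", i)
    d_ib <- delayed_sample("ib", i)
    stepped <- network_step(ns, net, d_ia, d_ii, d_ib, cmd[i, ], dt, npar)
    ns <- stepped$state
    u <- stepped$u
    a <- activation_step(a, u, dt, mus$tau_act_s, mus$tau_deact_s)
    cur <- rates_at(state, a)
    hist$ia[i, ] <- cur$ia; hist$ii[i, ] <- cur$ii; hist$ib[i, ] <- cur$ib
    out$theta[i, ] <- state$q; out$thetadot[i, ] <- state$qd
    out$u[i, ] <- u; out$a[i, ] <- a; out$force[i, ] <- cur$force
    out$ia[i, ] <- cur$ia; out$ii[i, ] <- cur$ii; out$ib[i, ] <- cur$ib
    hf <- if (i - 1 >= i_on && i - 1 < i_off) pf else c(0, 0)
    state <- dynamics_step(state, cur$force, dt, config$gravity, hf,
                           config$arm, mus)
  }
  out$theta[n_out, ] <- state$q; out$thetadot[n_out, ] <- state$qd
  for (f in c("u", "a", "force", "ia", "ii", "ib"))
    out[[f]][n_out, ] <- out[[f]][n_out - 1, ]
  out
}

#' The seven gravity environments of the gravity studies
#'
#' Four magnitudes (0.5, 1, 1.5, 2 g at upright direction) and four
#' directions (-45, 0, 45, 90 degrees at 1 g, 90 being the lying
#' position), with normal gravity shared between the two families: seven
#' distinct environments.
#'
#' @return Named list of `gravity_environment` objects.
#' @export
gravity_environments <- function() {
  envs <- list(
    g0.5 = gravity_environment(0.5, 0),
    g1.0 = gravity_environment(1.0, 0),
    g1.5 = gravity_environment(1.5, 0),
    g2.0 = gravity_environment(2.0, 0),
    rot_m45 = gravity_environment(1.0, -45),
    rot_45 = gravity_environment(1.0, 45),
    rot_90 = gravity_environment(1.0, 90)
  )
  envs
}

#' Sweep one pathway's synaptic strength (scenario S1)
#'
#' Runs one simulation per grid value with only the chosen pathway active
#' (all muscles share the weight; all other pathways at 0) and computes
#' kinematic and smoothness metrics against the configured target.
#'
#' @param pathway one of `pathway_kinds()`.
#' @param weight_grid numeric vector of weights in \[0, 1\].
#' @param base_config a `simulation_config` (its weight matrix is
#'   replaced).
#' @param emg optional `emg_set` for overlap metrics.
#' @return data.frame with one row per weight: `weight`, `rmse_deg`,
#'   `sal` and, when `emg` is given, `overlap_total_pct`.
#' @export
scenario_pathway_sweep <- function(pathway, weight_grid, base_config,
                                   emg = NULL) {
  stopifnot(pathway %in% pathway_kinds(),
            all(weight_grid >= 0), all(weight_grid <= 1))
  rows <- lapply(weight_grid, function(w) {
    args <- stats::setNames(list(w), pathway)
    cfg <- base_config
    cfg$weights <- do.call(synaptic_weights, args)
    tr <- run_simulation(cfg)
    row <- data.frame(
      weight = w,
      rmse_deg = trajectory_rmse(tr, cfg$target),
      sal = elbow_sal(tr)
    )
    if (!is.null(emg)) {
      ov <- emg_overlap(tr, emg)
      row$overlap_total_pct <- ov$overlap_total_pct
    }
    row
  })
  do.call(rbind, rows)
}

#' Find the instant of peak elbow flexion of an unperturbed run
#'
#' @param config a `simulation_config` (perturbation ignored).
#' @return Time (s) of the maximal elbow angle.
#' @export
peak_flexion_time <- function(config) {
  cfg <- config
  cfg$perturbation <- NULL
  tr <- run_simulation(cfg)
  tr$time_s[which.max(tr$elbow_deg)]
}

#' Perturbation-robustness sweep of one pathway (scenario S2)
#'
#' For each weight, runs a paired unperturbed and perturbed simulation
#' with a hand-force perturbation starting at the unperturbed run's peak
#' elbow flexion, and computes the elbow deviation metric on the perturbed
#' trace.
#'
#' @param pathway one of `pathway_kinds()`.
#' @param weight_grid numeric vector of weights in \[0, 1\].
#' @param base_config a `simulation_config`.
#' @param force_magnitude_n,direction,duration_s perturbation parameters
#'   (defaults 30 N, upward, 30 ms).
#' @return data.frame with `weight` and `deviation_deg`.
#' @export
scenario_perturbation <- function(pathway, weight_grid, base_config,
                                  force_magnitude_n = 30,
                                  direction = "upward",
                                  duration_s = 0.030) {
  stopifnot(pathway %in% pathway_kinds())
  rows <- lapply(weight_grid, function(w) {
    args <- stats::setNames(list(w), pathway)
    cfg <- base_config
    cfg$weights <- do.call(synaptic_weights, args)
    cfg$perturbation <- NULL
    onset <- peak_flexion_time(cfg)
    cfg$perturbation <- perturbation(force_magnitude_n, direction,
                                     onset, duration_s)
    tr <- run_simulation(cfg)
    data.frame(weight = w,
               deviation_deg = elbow_deviation(tr, onset))
  })
  do.call(rbind, rows)
}
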