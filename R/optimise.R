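#' Tracking loss with end-point activation penalty
#'
#' Sum of the per-joint mean squared errors (degrees) between simulated
#' and target trajectories, plus `w_pen` times the mean squared muscle
#' activation over the first and last `penalty_window_s` of the run
#' (penalising residual drive at the start and end of the movement).
#'
#' @param trace a `simulation_trace`.
#' @param target a `target_trajectory`.
#' @param w_pen penalty weight (default 5).
#' @param penalty_window_s window at each end (s, default 0.1).
#' @return Non-negative scalar loss.
#' @export
tracking_loss <- function(trace, target, w_pen = 5,
                          penalty_window_s = 0.1) {
  stopifnot(w_pen >= 0)
  sh_t <- stats::approx(target$time_s, target$shoulder_deg, trace$time_s,
                        rule = 2)$y
  el_t <- stats::approx(target$time_s, target$elbow_deg, trace$time_s,
                        rule = 2)$y
  kin <- mean((trace$shoulder_deg - sh_t)^2) +
    mean((trace$elbow_deg - el_t)^2)
  t_end <- max(trace$time_s)
  in_window <- trace$time_s <= penalty_window_s |
    trace$time_s >= t_end - penalty_window_s
  pen <- mean(rowMeans(trace$a[in_window, , drop = FALSE]^2))
  kin + w_pen * pen
}

#' Optimise the supraspinal sinusoid parameters (scenario S3)
#'
#' CMA-ES over the 8 command parameters (amplitude, frequency, phase,
#' offset for the flexor and extensor groups) within their admissible
#' bounds, minimising the tracking loss, with or without the minimal
#' spinal model engaged.
#'
#' @param target a `target_trajectory`.
#' @param gravity a `gravity_environment`.
#' @param with_minimal_sc logical: engage the minimal spinal model
#'   (Ia-MN + Ia-INa at full strength)?
#' @param budget_iterations CMA-ES generations.
#' @param seed integer seed.
#' @param dt_s integration step (s).
#' @param lambda optional population size override.
#' @return The [cma_es_minimise()] result, with `best_commands` (a
#'   `command_set`) added.
#' @export
optimise_supraspinal <- function(target, gravity = gravity_environment(),
                                 with_minimal_sc = TRUE,
                                 budget_iterations = 200, seed = 1L,
                                 dt_s = 0.001, lambda = NULL) {
  bounds <- supraspinal_bounds()
  weights <- if (with_minimal_sc) minimal_sc_weights() else
    synaptic_weights()
  fn <- function(x) {
    cfg <- simulation_config(target = target, weights = weights,
                             commands = command_set_from_vector(x),
                             gravity = gravity, dt_s = dt_s)
    tracking_loss(run_simulation(cfg), target)
  }
  res <- cma_es_minimise(fn, bounds[, "low"], bounds[, "high"],
                         seed = seed,
                         budget_iterations = budget_iterations,
                         lambda = lambda)
  res$best_commands <- command_set_from_vector(res$best_parameters)
  res
}

# Map the 4-dim group weight vector (IaMN_flex, IaMN_ext, IaINa_flex,
# IaINa_ext) to a full synaptic weight matrix. The anterior deltoid
# follows the flexor group (it is a flexor, albeit of the shoulder).
group_weight_matrix <- function(x) {
  grp <- elbow_groups()
  flex <- c(grp$flexor, "Delt_ant")
  ext <- grp$extensor
  iamn <- iaina <- stats::setNames(numeric(7), muscle_names())
  iamn[flex] <- x[1]; iamn[ext] <- x[2]
  iaina[flex] <- x[3]; iaina[ext] <- x[4]
  synaptic_weights(IaMN = iamn, IaINa = iaina, max_weight = 2)
}

#' Optimise the minimal-SC synaptic strengths (scenario S4)
#'
#' CMA-ES over four group-level weights -- the Ia-MN and Ia-INa strengths
#' shared across the flexor group and across the extensor group -- in
#' \[0, 2\], with the supraspinal commands held fixed.
#'
#' @param target a `target_trajectory`.
#' @param gravity a `gravity_environment`.
#' @param fixed_commands a `command_set` (typically the normal-gravity
#'   supraspinal optimum).
#' @param budget_iterations CMA-ES generations.
#' @param seed integer seed.
#' @param dt_s integration step (s).
#' @param lambda optional population size override.
#' @return The [cma_es_minimise()] result, with `best_weights` (a
#'   `synaptic_weights` matrix) added.
#' @export
optimise_weights <- function(target, gravity = gravity_environment(),
                             fixed_commands, budget_iterations = 200,
                             seed = 1L, dt_s = 0.001, lambda = NULL) {
  stopifnot(inherits(fixed_commands, "command_set"))
  fn <- function(x) {
    cfg <- simulation_config(target = target,
                             weights = group_weight_matrix(x),
                             commands = fixed_commands,
                             gravity = gravity, dt_s = dt_s)
    tracking_loss(run_simulation(cfg), target)
  }
  res <- cma_es_minimise(fn, rep(0, 4), rep(2, 4), seed = seed,
                         budget_iterations = budget_iterations,
                         x0 = rep(1, 4), lambda = lambda)
  res$best_weights <- group_weight_matrix(res$best_parameters)
  res
}
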