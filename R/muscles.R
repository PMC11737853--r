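#' @useDynLib reflexarm, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Muscle roster of the planar arm
#'
#' Seven Hill-type muscles actuate the two joints: the anterior deltoid
#' (shoulder flexor), the long triceps head (shoulder extensor and elbow
#' extensor, biarticular), the lateral and medial triceps heads (elbow
#' extensors), the long and short biceps heads (elbow flexors; the long head
#' is biarticular and also flexes the shoulder) and the brachialis (elbow
#' flexor).
#'
#' @return Character vector of the seven muscle names, in canonical order.
#' @export
muscle_names <- function() {
  c("Delt_ant", "Tri_long", "Tri_lat", "Tri_med",
    "Bic_long", "Bic_short", "Brach")
}

#' Elbow flexor and extensor muscle groups
#'
#' @return Named list with `flexor` and `extensor` character vectors.
#' @export
elbow_groups <- function() {
  list(flexor   = c("Bic_long", "Bic_short", "Brach"),
       extensor = c("Tri_long", "Tri_lat", "Tri_med"))
}

#' Default muscle parameter table
#'
#' Maximal isometric forces and optimal fiber lengths are literature-typical
#' adult upper-limb values; moment arms are constant (straight-line paths
#' with a rigid tendon), signed so that positive moment arms produce flexion
#' torque. The reference posture at which each fiber sits at its reference
#' (optimal) length defaults to the rest posture of the baseline movement
#' (shoulder 0 deg, elbow 20 deg), so the passive and reflex-controlled arm
#' is anchored near its resting position -- spindle rates sit at their
#' 10 Hz baseline there and stretch reflexes pull back toward it.
#'
#' @param reference_shoulder_deg,reference_elbow_deg posture (degrees) at
#'   which `reference_length_mm` is attained.
#' @return A data.frame with one row per muscle: `name`, `f_max_n`,
#'   `optimal_fiber_length_mm`, `pennation_rad`, `moment_arm_shoulder_mm`,
#'   `moment_arm_elbow_mm`, `tau_act_s`, `tau_deact_s`,
#'   `reference_length_mm`.
#' @export
default_muscle_parameters <- function(reference_shoulder_deg = 0,
                                      reference_elbow_deg = 20) {
  df <- data.frame(
    name = muscle_names(),
    f_max_n = c(1000, 800, 600, 600, 625, 435, 990),
    optimal_fiber_length_mm = c(110, 134, 114, 114, 116, 132, 86),
    pennation_rad = rep(0, 7),
    moment_arm_shoulder_mm = c(25, -25, 0, 0, 25, 0, 0),
    moment_arm_elbow_mm = c(0, -20, -20, -20, 20, 20, 20),
    tau_act_s = rep(0.010, 7),
    tau_deact_s = rep(0.040, 7),
    stringsAsFactors = FALSE
  )
  df$reference_length_mm <- df$optimal_fiber_length_mm
  attr(df, "reference_posture_deg") <- c(shoulder = reference_shoulder_deg,
                                         elbow = reference_elbow_deg)
  class(df) <- c("muscle_parameters", "data.frame")
  df
}

validate_muscle_parameters <- function(params) {
  stopifnot(is.data.frame(params),
            identical(params$name, muscle_names()),
            all(params$f_max_n > 0),
            all(params$optimal_fiber_length_mm > 0))
  ma_e <- params$moment_arm_elbow_mm
  ma_s <- params$moment_arm_shoulder_mm
  names(ma_e) <- names(ma_s) <- params$name
  if (ma_e[["Delt_ant"]] != 0)
    stop("Delt_ant must have zero elbow moment arm")
  mono_elbow <- c("Tri_lat", "Tri_med", "Bic_short", "Brach")
  if (any(ma_s[mono_elbow] != 0))
    stop("Tri_lat, Tri_med, Bic_short and Brach must have zero shoulder moment arm")
  biart <- c("Bic_long", "Tri_long")
  if (any(ma_s[biart] == 0) || any(ma_e[biart] == 0))
    stop("Bic_long and Tri_long are biarticular: both moment arms must be nonzero")
  invisible(params)
}

#' Antagonist and synergist relations between muscles
#'
#' Encodes the pairwise relation table of the seven-muscle arm: 6 antagonist
#' pairs and 7 synergist pairs; the remaining 8 of the 21 unordered pairs
#' are unrelated. Relations are symmetric and no pair is both.
#'
#' @return List with components `antagonists` and `synergists`, each a
#'   two-column character matrix of unordered pairs, plus logical adjacency
#'   matrices `antagonist_matrix` and `synergist_matrix` (7 x 7, named).
#' @export
muscle_relations <- function() {
  ant <- rbind(
    c("Delt_ant", "Tri_long"),
    c("Tri_long", "Bic_long"),
    c("Tri_lat",  "Bic_short"),
    c("Tri_lat",  "Brach"),
    c("Tri_med",  "Bic_short"),
    c("Tri_med",  "Brach")
  )
  syn <- rbind(
    c("Delt_ant", "Bic_long"),
    c("Tri_long", "Tri_lat"),
    c("Tri_long", "Tri_med"),
    c("Tri_lat",  "Tri_med"),
    c("Bic_long", "Bic_short"),
    c("Bic_long", "Brach"),
    c("Bic_short", "Brach")
  )
  nm <- muscle_names()
  to_mat <- function(pairs) {
    m <- matrix(FALSE, 7, 7, dimnames = list(nm, nm))
    for (i in seq_len(nrow(pairs))) {
      m[pairs[i, 1], pairs[i, 2]] <- TRUE
      m[pairs[i, 2], pairs[i, 1]] <- TRUE
    }
    m
  }
  am <- to_mat(ant)
  sm <- to_mat(syn)
  stopifnot(!any(am & sm))
  list(antagonists = ant, synergists = syn,
       antagonist_matrix = am, synergist_matrix = sm)
}

#' Muscle fiber length and velocity from joint state
#'
#' Constant-moment-arm path model: fiber length decreases linearly with
#' joint excursion weighted by the (signed) moment arms,
#' `l = l_ref - sum_j ma_j (theta_j - theta_ref_j)`, and fiber velocity
#' follows by the chain rule, `ldot = -sum_j ma_j thetadot_j`. Lengths are
#' floored at half the optimal fiber length.
#'
#' @param theta_shoulder_rad,theta_elbow_rad joint angles (radians, flexion
#'   positive).
#' @param thetadot_shoulder_rad,thetadot_elbow_rad joint velocities (rad/s).
#' @param params muscle parameter table (see
#'   [default_muscle_parameters()]).
#' @return List with numeric vectors `length_mm` and `velocity_mm_s`
#'   (named by muscle).
#' @export
muscle_geometry <- function(theta_shoulder_rad, theta_elbow_rad,
                            thetadot_shoulder_rad = 0,
                            thetadot_elbow_rad = 0,
                            params = default_muscle_parameters()) {
  stopifnot(is.finite(theta_shoulder_rad), is.finite(theta_elbow_rad))
  ref <- attr(params, "reference_posture_deg") * pi / 180
  d_sh <- theta_shoulder_rad - ref[["shoulder"]]
  d_el <- theta_elbow_rad - ref[["elbow"]]
  len <- params$reference_length_mm -
    params$moment_arm_shoulder_mm * d_sh -
    params$moment_arm_elbow_mm * d_el
  len <- pmax(len, 0.5 * params$optimal_fiber_length_mm)
  vel <- -params$moment_arm_shoulder_mm * thetadot_shoulder_rad -
    params$moment_arm_elbow_mm * thetadot_elbow_rad
  list(length_mm = stats::setNames(len, params$name),
       velocity_mm_s = stats::setNames(vel, params$name))
}

# Normalised Hill curves. ltilde = l / l0, vtilde = ldot / (10 l0 / s).
hill_fl <- function(ltilde) exp(-((ltilde - 1) / 0.45)^2)

hill_fv <- function(vtilde) {
  ifelse(vtilde < 0,
         pmax(0, (1 + vtilde) / (1 - 4 * vtilde)),
         1 + 0.4 * vtilde / (vtilde + 0.075))
}

hill_fp <- function(ltilde) {
  ifelse(ltilde <= 1, 0, (exp(5 * (ltilde - 1)) - 1) / (exp(2.5) - 1))
}

#' Hill-type muscle force
#'
#' `F = F_max (a f_l(l/l0) f_v(ldot/v_max) + f_p(l/l0)) cos(pennation)`,
#' floored at zero. The active force-length curve is a Gaussian with width
#' 0.45, the force-velocity curve the classic Hill hyperbola (maximal
#' shortening velocity 10 optimal lengths per second, eccentric plateau
#' 1.4) and the passive curve an exponential engaging beyond the optimal
#' length.
#'
#' @param a activation in \[0, 1\] (scalar or per-muscle vector).
#' @param length_mm,velocity_mm_s fiber lengths (mm) and velocities (mm/s).
#' @param params muscle parameter table.
#' @return Named numeric vector of muscle forces (N), all non-negative.
#' @export
hill_force <- function(a, length_mm, velocity_mm_s,
                       params = default_muscle_parameters()) {
  if (any(a < 0) || any(a > 1)) stop("activation 'a' must lie in [0, 1]")
  if (any(length_mm < 0)) stop("fiber length must be non-negative")
  l0 <- params$optimal_fiber_length_mm
  ltilde <- length_mm / l0
  vtilde <- velocity_mm_s / (10 * l0)
  f <- params$f_max_n *
    (a * hill_fl(ltilde) * hill_fv(vtilde) + hill_fp(ltilde)) *
    cos(params$pennation_rad)
  stats::setNames(pmax(f, 0), params$name)
}

#' One step of first-order activation dynamics
#'
#' Calcium activation tracks neural excitation with asymmetric time
#' constants: `tau_act` while excitation exceeds activation, `tau_deact`
#' otherwise. The update is the exact exponential solution for a constant
#' excitation over the step, so the step response reaches 1 - exp(-1) of
#' its asymptote after one time constant regardless of `dt`.
#'
#' @param a current activation(s) in \[0, 1\].
#' @param u excitation(s) in \[0, 1\].
#' @param dt step (s).
#' @param tau_act,tau_deact time constants (s).
#' @return Updated activation(s), clamped to \[0, 1\].
#' @export
activation_step <- function(a, u, dt, tau_act = 0.010, tau_deact = 0.040) {
  stopifnot(dt > 0)
  tau <- ifelse(u > a, tau_act, tau_deact)
  pmin(pmax(u + (a - u) * exp(-dt / tau), 0), 1)
}
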