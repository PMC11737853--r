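#' Default rigid-body parameters of the planar two-link arm
#'
#' Literature-typical adult values: upper arm 0.30 m / 2.0 kg, forearm plus
#' hand 0.35 m / 1.7 kg, centres of mass at 45% of segment length from the
#' proximal joint, segment inertias of uniform rods about their centre of
#' mass, viscous damping 0.15 N m s/rad per joint, and soft joint limits.
#' Angles are measured with flexion positive: the shoulder angle from the
#' hanging (downward) direction, the elbow angle from full extension.
#'
#' @return List of arm parameters (SI units encoded in names).
#' @export
default_arm_parameters <- function() {
  list(
    upper_arm_length_m = 0.30,
    forearm_length_m = 0.35,
    upper_arm_mass_kg = 2.0,
    forearm_mass_kg = 1.7,
    com_fraction = 0.45,
    upper_arm_inertia_kgm2 = 2.0 * 0.30^2 / 12,
    forearm_inertia_kgm2 = 1.7 * 0.35^2 / 12,
    joint_damping_nms = 0.15,
    shoulder_limits_rad = c(-60, 150) * pi / 180,
    elbow_limits_rad = c(0, 150) * pi / 180,
    limit_stiffness_nm_rad = 50
  )
}

validate_arm_parameters <- function(p) {
  stopifnot(p$upper_arm_length_m > 0, p$forearm_length_m > 0,
            p$upper_arm_mass_kg > 0, p$forearm_mass_kg > 0,
            p$upper_arm_inertia_kgm2 > 0, p$forearm_inertia_kgm2 > 0,
            p$shoulder_limits_rad[1] < p$shoulder_limits_rad[2],
            p$elbow_limits_rad[1] < p$elbow_limits_rad[2])
  invisible(p)
}

#' Gravity acceleration vector for a gravity environment
#'
#' Baseline gravity (0, -9.81 * magnitude_scale) m/s^2 rotated by
#' `direction_rotation_deg` about the out-of-plane axis; a rotation of
#' 90 degrees aligns gravity with the body axis (lying position).
#'
#' @param env list with `magnitude_scale` (dimensionless, >= 0) and
#'   `direction_rotation_deg` (degrees).
#' @return Numeric 2-vector (x, y) in m/s^2.
#' @export
gravity_vector <- function(env = gravity_environment()) {
  stopifnot(env$magnitude_scale >= 0)
  g0 <- c(0, -9.81 * env$magnitude_scale)
  phi <- env$direction_rotation_deg * pi / 180
  # positive rotation tilts gravity toward -x: +90 deg maps (0, -g) to
  # (-g, 0), gravity along the body axis (lying position)
  rot <- matrix(c(cos(phi), -sin(phi), sin(phi), cos(phi)), 2, 2)
  as.numeric(rot %*% g0)
}

#' Construct a gravity environment
#'
#' @param magnitude_scale multiple of g = 9.81 m/s^2.
#' @param direction_rotation_deg rotation of the gravity direction about
#'   the out-of-plane axis (degrees); 90 corresponds to the lying position.
#' @return List of class `gravity_environment`.
#' @export
gravity_environment <- function(magnitude_scale = 1,
                                direction_rotation_deg = 0) {
  stopifnot(magnitude_scale >= 0)
  structure(list(magnitude_scale = magnitude_scale,
                 direction_rotation_deg = direction_rotation_deg),
            class = "gravity_environment")
}

# Mass matrix, Coriolis/centrifugal torques and gravity torques of the
# two-link chain in relative coordinates q = (theta_sh, theta_elb); the
# absolute segment angles from the downward vertical are phi1 = q1 and
# phi2 = q1 + q2.
arm_mass_matrix <- function(q, p) {
  r1 <- p$com_fraction * p$upper_arm_length_m
  r2 <- p$com_fraction * p$forearm_length_m
  m1 <- p$upper_arm_mass_kg; m2 <- p$forearm_mass_kg
  L1 <- p$upper_arm_length_m
  I1 <- p$upper_arm_inertia_kgm2; I2 <- p$forearm_inertia_kgm2
  c2 <- cos(q[2])
  M11 <- m1 * r1^2 + I1 + m2 * (L1^2 + r2^2 + 2 * L1 * r2 * c2) + I2
  M12 <- m2 * (r2^2 + L1 * r2 * c2) + I2
  M22 <- m2 * r2^2 + I2
  matrix(c(M11, M12, M12, M22), 2, 2)
}

arm_coriolis <- function(q, qd, p) {
  r2 <- p$com_fraction * p$forearm_length_m
  h <- -p$forearm_mass_kg * p$upper_arm_length_m * r2 * sin(q[2])
  c(h * qd[2] * (2 * qd[1] + qd[2]), -h * qd[1]^2)
}

arm_gravity_torque <- function(q, g, p) {
  r1 <- p$com_fraction * p$upper_arm_length_m
  r2 <- p$com_fraction * p$forearm_length_m
  m1 <- p$upper_arm_mass_kg; m2 <- p$forearm_mass_kg
  L1 <- p$upper_arm_length_m
  phi1 <- q[1]; phi2 <- q[1] + q[2]
  # dV/dq with V = -g . (m1 c1 + m2 c2); segment direction (sin phi, -cos phi)
  dc1 <- r1 * c(cos(phi1), sin(phi1))
  dc2_1 <- L1 * c(cos(phi1), sin(phi1)) + r2 * c(cos(phi2), sin(phi2))
  dc2_2 <- r2 * c(cos(phi2), sin(phi2))
  c(-sum(g * (m1 * dc1 + m2 * dc2_1)), -sum(g * (m2 * dc2_2)))
}

arm_hand_jacobian <- function(q, p) {
  L1 <- p$upper_arm_length_m; L2 <- p$forearm_length_m
  phi1 <- q[1]; phi2 <- q[1] + q[2]
  cbind(L1 * c(cos(phi1), sin(phi1)) + L2 * c(cos(phi2), sin(phi2)),
        L2 * c(cos(phi2), sin(phi2)))
}

arm_limit_torque <- function(q, p) {
  lim <- rbind(p$shoulder_limits_rad, p$elbow_limits_rad)
  k <- p$limit_stiffness_nm_rad
  -k * pmax(q - lim[, 2], 0) + k * pmax(lim[, 1] - q, 0)
}

#' One semi-implicit Euler step of the arm dynamics
#'
#' Advances the standard two-link planar equations of motion (inertia
#' matrix, Coriolis/centrifugal terms, gravity, viscous joint damping, soft
#' joint-limit torques). Joint torques are the moment-arm-weighted sum of
#' muscle forces plus the Jacobian-transpose torque of any active hand
#' force. Velocities are updated first, then positions with the new
#' velocities (semi-implicit Euler).
#'
#' @param state list with `q` (radians, c(shoulder, elbow)) and `qd`
#'   (rad/s).
#' @param muscle_forces_n named per-muscle forces (N); may be zero.
#' @param dt step (s).
#' @param env gravity environment.
#' @param hand_force_n optional world-frame force (N, 2-vector) applied at
#'   the hand.
#' @param arm arm parameter list.
#' @param muscles muscle parameter table.
#' @return Updated state list (`q`, `qd`).
#' @export
dynamics_step <- function(state, muscle_forces_n, dt,
                          env = gravity_environment(),
                          hand_force_n = c(0, 0),
                          arm = default_arm_parameters(),
                          muscles = default_muscle_parameters()) {
  stopifnot(dt > 0, all(is.finite(muscle_forces_n)))
  q <- state$q; qd <- state$qd
  if (any(!is.finite(q)) || any(!is.finite(qd)))
    stop("non-finite arm state: simulation aborted")
  g <- gravity_vector(env)
  # moment arms in metres: torque = sum_m ma_m F_m
  tau_m <- c(
    sum(muscles$moment_arm_shoulder_mm * 1e-3 * muscle_forces_n),
    sum(muscles$moment_arm_elbow_mm * 1e-3 * muscle_forces_n)
  )
  tau <- tau_m +
    as.numeric(t(arm_hand_jacobian(q, arm)) %*% hand_force_n) +
    arm_limit_torque(q, arm) -
    arm$joint_damping_nms * qd
  rhs <- tau - arm_coriolis(q, qd, arm) - arm_gravity_torque(q, g, arm)
  qdd <- solve(arm_mass_matrix(q, arm), rhs)
  qd_new <- qd + dt * qdd
  q_new <- q + dt * qd_new
  list(q = q_new, qd = qd_new)
}
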