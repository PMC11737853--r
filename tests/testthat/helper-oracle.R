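# Independent double-pendulum oracle in ABSOLUTE segment angles
# (phi1, phi2), a different parameterisation from the engine's relative
# coordinates, integrated with RK4 at a 10x smaller step.
pendulum_oracle <- function(q0, qd0, g, p, t_end, dt) {
  r1 <- p$com_fraction * p$upper_arm_length_m
  r2 <- p$com_fraction * p$forearm_length_m
  m1 <- p$upper_arm_mass_kg; m2 <- p$forearm_mass_kg
  L1 <- p$upper_arm_length_m
  I1 <- p$upper_arm_inertia_kgm2; I2 <- p$forearm_inertia_kgm2
  deriv <- function(s) {
    phi <- s[1:2]; phid <- s[3:4]
    A11 <- m1 * r1^2 + I1 + m2 * L1^2
    A22 <- m2 * r2^2 + I2
    A12 <- m2 * L1 * r2 * cos(phi[2] - phi[1])
    k <- m2 * L1 * r2 * sin(phi[2] - phi[1])
    dV1 <- -sum(g * ((m1 * r1 + m2 * L1) * c(cos(phi[1]), sin(phi[1]))))
    dV2 <- -sum(g * (m2 * r2 * c(cos(phi[2]), sin(phi[2]))))
    rhs <- c(k * phid[2]^2 - dV1, -k * phid[1]^2 - dV2)
    A <- matrix(c(A11, A12, A12, A22), 2, 2)
    c(phid, solve(A, rhs))
  }
  s <- c(q0[1], q0[1] + q0[2], qd0[1], qd0[1] + qd0[2])
  for (i in seq_len(round(t_end / dt))) {
    k1 <- deriv(s)
    k2 <- deriv(s + dt / 2 * k1)
    k3 <- deriv(s + dt / 2 * k2)
    k4 <- deriv(s + dt * k3)
    s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  list(q = c(s[1], s[2] - s[1]), qd = c(s[3], s[4] - s[3]))
}

frictionless_arm <- function() {
  p <- default_arm_parameters()
  p$joint_damping_nms <- 0
  p$shoulder_limits_rad <- c(-100, 100)
  p$elbow_limits_rad <- c(-100, 100)
  p
}

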