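#' One-cycle sinusoidal supraspinal command
#'
#' A single cycle of `a sin(2 pi f t + phi) + d`, clipped to \[0, 1\];
#' after one full period (t >= 1/f) the command holds its offset d. One
#' command is defined per elbow muscle group (flexor or extensor),
#' representing the reach and the return to the initial position as one
#' motor primitive.
#'
#' @param amplitude dimensionless, admissible range \[0.05, 0.7\].
#' @param frequency_hz Hz, admissible range \[0.1, 0.8\].
#' @param phase_rad radians, admissible range \[0, 2 pi\].
#' @param offset dimensionless, admissible range \[0, 0.1\].
#' @param group "elbow_flexor" or "elbow_extensor".
#' @return List of class `sinusoid_command`.
#' @export
sinusoid_command <- function(amplitude, frequency_hz, phase_rad = 0,
                             offset = 0,
                             group = c("elbow_flexor", "elbow_extensor")) {
  if (frequency_hz <= 0) stop("frequency_hz must be positive")
  structure(list(amplitude = amplitude, frequency_hz = frequency_hz,
                 phase_rad = phase_rad, offset = offset,
                 group = match.arg(group)),
            class = "sinusoid_command")
}

#' Supraspinal parameter bounds
#'
#' Admissible optimisation ranges: amplitude \[0.05, 0.7\], frequency
#' \[0.1, 0.8\] Hz, phase \[0, 2 pi\], offset \[0, 0.1\].
#'
#' @return Two-column matrix (low, high), rows named
#'   a_F, f_F, phi_F, d_F, a_E, f_E, phi_E, d_E.
#' @export
supraspinal_bounds <- function() {
  b <- rbind(a = c(0.05, 0.7), f = c(0.1, 0.8),
             phi = c(0, 2 * pi), d = c(0, 0.1))
  out <- rbind(b, b)
  rownames(out) <- c("a_F", "f_F", "phi_F", "d_F",
                     "a_E", "f_E", "phi_E", "d_E")
  colnames(out) <- c("low", "high")
  out
}

#' Evaluate a command at time t
#'
#' @param cmd a `sinusoid_command`.
#' @param t_s time(s) in seconds, >= 0.
#' @return Command value(s) in \[0, 1\].
#' @export
command_value <- function(cmd, t_s) {
  active <- t_s < 1 / cmd$frequency_hz
  raw <- ifelse(active,
                cmd$amplitude *
                  sin(2 * pi * cmd$frequency_hz * t_s + cmd$phase_rad) +
                  cmd$offset,
                cmd$offset)
  pmin(pmax(raw, 0), 1)
}

#' Command set for both elbow groups
#'
#' The three elbow flexors (Bic_long, Bic_short, Brach) receive the flexor
#' command, the three elbow extensors (Tri_long, Tri_lat, Tri_med) the
#' extensor command, and the anterior deltoid receives no supraspinal
#' command (it does not actuate the elbow).
#'
#' @param flexor,extensor `sinusoid_command` objects.
#' @return List of class `command_set`.
#' @export
command_set <- function(flexor, extensor) {
  stopifnot(inherits(flexor, "sinusoid_command"),
            inherits(extensor, "sinusoid_command"))
  structure(list(flexor = flexor, extensor = extensor),
            class = "command_set")
}

#' Build a command set from an 8-parameter vector
#'
#' Parameter order: a_F, f_F, phi_F, d_F, a_E, f_E, phi_E, d_E (the vector
#' the supraspinal optimisation searches).
#'
#' @param x numeric length-8 vector.
#' @return A `command_set`.
#' @export
command_set_from_vector <- function(x) {
  stopifnot(length(x) == 8)
  command_set(
    sinusoid_command(x[1], x[2], x[3], x[4], group = "elbow_flexor"),
    sinusoid_command(x[5], x[6], x[7], x[8], group = "elbow_extensor")
  )
}

#' Zero command set (no supraspinal drive)
#'
#' @return A `command_set` whose value is 0 at all times.
#' @export
zero_command_set <- function() {
  command_set(
    sinusoid_command(0, 1, 0, 0, group = "elbow_flexor"),
    sinusoid_command(0, 1, 0, 0, group = "elbow_extensor")
  )
}

#' Per-muscle command matrix on a time grid
#'
#' @param cmds a `command_set`.
#' @param t_s numeric vector of times (s).
#' @return length(t_s) x 7 matrix of command values, columns named by
#'   muscle.
#' @export
command_matrix <- function(cmds, t_s) {
  grp <- elbow_groups()
  out <- matrix(0, length(t_s), 7,
                dimnames = list(NULL, muscle_names()))
  out[, grp$flexor] <- command_value(cmds$flexor, t_s)
  out[, grp$extensor] <- command_value(cmds$extensor, t_s)
  out[, "Delt_ant"] <- 0
  out
}
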