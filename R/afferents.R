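#' Default afferent (muscle spindle / Golgi tendon) parameters
#'
#' Prochazka-style rate models for Ia, II and Ib fibers with a tonic
#' baseline of 10 Hz and a fixed sensory transmission delay of 30 ms.
#' Normalisation maxima are fixed at construction from a physiological
#' envelope (|velocity| up to 300 mm/s, |length - l0| up to 50 mm), so the
#' effective feedback gain is constant within and across runs.
#'
#' @return List of afferent parameters.
#' @export
default_afferent_parameters <- function() {
  p <- list(
    ia_velocity_gain = 4.3,     # Hz per (mm/s)^0.6
    ia_velocity_exponent = 0.6,
    ia_length_gain = 2,         # Hz/mm
    ii_length_gain = 13.5,      # Hz/mm
    baseline_rate_hz = 10,
    velocity_floor_mm_s = 0.01,
    delay_s = 0.030,
    envelope_velocity_mm_s = 300,
    envelope_length_mm = 50
  )
  p$normalisation_max_hz <- c(
    Ia = p$ia_velocity_gain * p$envelope_velocity_mm_s^p$ia_velocity_exponent +
      p$ia_length_gain * p$envelope_length_mm + p$baseline_rate_hz,
    II = p$ii_length_gain * p$envelope_length_mm + p$baseline_rate_hz
  )
  p
}

#' Raw afferent firing rates
#'
#' Prochazka fiber rate models:
#' `r_Ia = sgn(v) * 4.3 * max(|v|, 0.01)^0.6 + 2 (l - l0) + 10` (Hz),
#' `r_II = 13.5 (l - l0) + 10` (Hz), and `r_Ib = F / F_max`
#' (dimensionless). Lengths in mm, velocities in mm/s. At the optimal
#' length with zero velocity both spindle rates equal the 10 Hz baseline
#' (sgn(0) = 0 removes the velocity term).
#'
#' @param length_mm,velocity_mm_s fiber length (mm) and velocity (mm/s).
#' @param force_n muscle force (N).
#' @param optimal_length_mm optimal fiber length l0 (mm).
#' @param f_max_n maximal isometric force (N).
#' @param params afferent parameter list.
#' @return List with numeric `ia_hz`, `ii_hz`, `ib` (vectorised over
#'   muscles).
#' @export
afferent_rates <- function(length_mm, velocity_mm_s, force_n,
                           optimal_length_mm, f_max_n,
                           params = default_afferent_parameters()) {
  stopifnot(all(length_mm > 0))
  dl <- length_mm - optimal_length_mm
  v <- velocity_mm_s
  ia <- sign(v) * params$ia_velocity_gain *
    pmax(abs(v), params$velocity_floor_mm_s)^params$ia_velocity_exponent +
    params$ia_length_gain * dl + params$baseline_rate_hz
  ii <- params$ii_length_gain * dl + params$baseline_rate_hz
  ib <- force_n / f_max_n
  list(ia_hz = ia, ii_hz = ii, ib = ib)
}

#' Normalise a raw afferent rate to \[0, 1\]
#'
#' Divides by the fixed per-fiber-type maximum and clips to \[0, 1\];
#' negative raw rates clip to 0 (firing rates cannot be negative). Ib is
#' already the force ratio and passes through with clipping only.
#'
#' @param raw raw rate (Hz for Ia/II, dimensionless for Ib).
#' @param fiber_type one of "Ia", "II", "Ib".
#' @param params afferent parameter list.
#' @return Value(s) in \[0, 1\].
#' @export
normalise_rate <- function(raw, fiber_type = c("Ia", "II", "Ib"),
                           params = default_afferent_parameters()) {
  fiber_type <- match.arg(fiber_type)
  x <- if (fiber_type == "Ib") raw else
    raw / params$normalisation_max_hz[[fiber_type]]
  pmin(pmax(x, 0), 1)
}

#' Exact ring-buffer delay line
#'
#' Stores past samples on the integration grid so that a read at time t
#' returns the value pushed at t - delay, exact to the step. Before one
#' full delay has elapsed the initial fill value is returned (delay lines
#' are pre-filled with the t = 0 sample to avoid startup transients).
#'
#' @param delay_s delay (s); must be a non-negative integer multiple of
#'   `dt_s`.
#' @param dt_s integration step (s).
#' @param initial fill value.
#' @return Object of class `delay_line`.
#' @export
delay_line <- function(delay_s, dt_s, initial = 0) {
  stopifnot(delay_s >= 0, dt_s > 0)
  steps <- delay_s / dt_s
  if (abs(steps - round(steps)) > 1e-9)
    stop("delay must be an integer multiple of dt")
  steps <- as.integer(round(steps))
  structure(
    list(buffer = rep(as.numeric(initial), max(steps, 1)),
         depth = steps, pos = 1L),
    class = "delay_line"
  )
}

#' Push a sample into a delay line and read the delayed sample
#'
#' @param line a `delay_line`.
#' @param new_sample value entering the line now.
#' @return List with `value` (the sample from `delay` seconds ago) and
#'   `line` (updated delay line).
#' @export
delayed <- function(line, new_sample) {
  if (line$depth == 0L)
    return(list(value = new_sample, line = line))
  out <- line$buffer[line$pos]
  line$buffer[line$pos] <- new_sample
  line$pos <- if (line$pos == line$depth) 1L else line$pos + 1L
  list(value = out, line = line)
}
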