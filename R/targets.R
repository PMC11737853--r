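#' Target trajectory specification
#'
#' Describes a one-cycle reach-and-return joint target. The two baseline
#' movements are an elbow flexion-extension of 2.8 s duration and 78 deg
#' elbow range of motion, and a circular movement of 1.3 s and 40 deg
#' elbow ROM.
#'
#' @param kind "flexion_extension" or "circular".
#' @param duration_s movement duration (s), > 0.
#' @param elbow_rom_deg elbow range of motion (deg), > 0.
#' @param elbow_start_deg elbow angle at movement start (deg).
#' @param shoulder_amplitude_deg amplitude of the shoulder excursion (deg).
#' @param shoulder_start_deg shoulder angle at movement start (deg).
#' @param sample_rate_hz target sampling rate (Hz), > 0.
#' @return List of class `trajectory_spec`.
#' @export
trajectory_spec <- function(kind = c("flexion_extension", "circular"),
                            duration_s = 2.8,
                            elbow_rom_deg = 78,
                            elbow_start_deg = 20,
                            shoulder_amplitude_deg = 10,
                            shoulder_start_deg = 0,
                            sample_rate_hz = 100) {
  kind <- match.arg(kind)
  if (duration_s <= 0) stop("duration_s must be positive")
  if (elbow_rom_deg <= 0) stop("elbow_rom_deg must be positive")
  if (sample_rate_hz <= 0) stop("sample_rate_hz must be positive")
  structure(list(kind = kind, duration_s = duration_s,
                 elbow_rom_deg = elbow_rom_deg,
                 elbow_start_deg = elbow_start_deg,
                 shoulder_amplitude_deg = shoulder_amplitude_deg,
                 shoulder_start_deg = shoulder_start_deg,
                 sample_rate_hz = sample_rate_hz),
            class = "trajectory_spec")
}

#' Baseline trajectory specs
#'
#' The default flexion-extension target (2.8 s, 78 deg elbow ROM) and the
#' default circular target (1.3 s, 40 deg elbow ROM).
#'
#' @name baseline_specs
#' @return A `trajectory_spec`.
#' @export
baseline_flexion_extension_spec <- function() {
  trajectory_spec("flexion_extension", duration_s = 2.8, elbow_rom_deg = 78)
}

#' @rdname baseline_specs
#' @export
baseline_circular_spec <- function() {
  trajectory_spec("circular", duration_s = 1.3, elbow_rom_deg = 40)
}

# Minimum-jerk scalar profile from 0 to 1 on s in [0, 1] (10-15-6 quintic):
# zero velocity and acceleration at both endpoints.
min_jerk <- function(s) 10 * s^3 - 15 * s^4 + 6 * s^5

#' Generate a target joint trajectory
#'
#' For a flexion-extension spec the elbow follows a minimum-jerk rise from
#' `elbow_start_deg` to `elbow_start_deg + elbow_rom_deg` over the first
#' half of the movement and a minimum-jerk return over the second half;
#' the shoulder performs the same reach-and-return shape scaled to
#' `shoulder_amplitude_deg`. For a circular spec the elbow follows a raised
#' cosine (one period) and the shoulder a sine of the same period, a 90 deg
#' phase lag that closes the hand path into a loop. Both joints return
#' exactly to their start angles.
#'
#' @param spec a `trajectory_spec`.
#' @return A data.frame of class `target_trajectory` with columns
#'   `time_s`, `shoulder_deg`, `elbow_deg`; `round(duration * rate) + 1`
#'   rows.
#' @export
make_target <- function(spec = baseline_flexion_extension_spec()) {
  stopifnot(inherits(spec, "trajectory_spec"))
  n <- round(spec$duration_s * spec$sample_rate_hz) + 1
  t <- seq(0, spec$duration_s, length.out = n)
  s <- t / spec$duration_s
  if (spec$kind == "flexion_extension") {
    up <- s <= 0.5
    shape <- ifelse(up, min_jerk(2 * s), min_jerk(2 - 2 * s))
    elbow <- spec$elbow_start_deg + spec$elbow_rom_deg * shape
    shoulder <- spec$shoulder_start_deg + spec$shoulder_amplitude_deg * shape
  } else {
    elbow <- spec$elbow_start_deg +
      spec$elbow_rom_deg / 2 * (1 - cos(2 * pi * s))
    shoulder <- spec$shoulder_start_deg +
      spec$shoulder_amplitude_deg * sin(2 * pi * s)
  }
  out <- data.frame(time_s = t, shoulder_deg = shoulder, elbow_deg = elbow)
  attr(out, "spec") <- spec
  class(out) <- c("target_trajectory", "data.frame")
  out
}

#' Synthetic EMG specification
#'
#' Stand-in for recorded surface EMG: smooth per-muscle bursts phase-locked
#' to the sign of the elbow acceleration, additive zero-mean noise and a
#' constant-plateau maximal-voluntary-contraction (MVC) trace per muscle.
#'
#' @param burst_width_fraction burst width as a fraction of the movement
#'   duration, in (0, 1).
#' @param noise_sd additive Gaussian noise sd (normalised units).
#' @param mvc_scale ratio of the MVC plateau to the burst peak, >= 1.
#' @param seed integer RNG seed; the generator is a pure function of
#'   (target, spec).
#' @return List of class `synthetic_emg_spec`.
#' @export
synthetic_emg_spec <- function(burst_width_fraction = 0.15,
                               noise_sd = 0.05, mvc_scale = 1.25,
                               seed = 1L) {
  stopifnot(burst_width_fraction > 0, burst_width_fraction < 1,
            noise_sd >= 0, mvc_scale >= 1)
  structure(list(burst_width_fraction = burst_width_fraction,
                 noise_sd = noise_sd, mvc_scale = mvc_scale,
                 seed = as.integer(seed)),
            class = "synthetic_emg_spec")
}

# Smooth non-negative bump (Hann window) of half-width w centred at c.
hann_bump <- function(t, centre, width) {
  x <- (t - centre) / width
  ifelse(abs(x) <= 0.5, cos(pi * x)^2, 0)
}

#' Generate synthetic EMG-like signals for a target trajectory
#'
#' Flexor-group muscles burst around the centres of intervals of positive
#' elbow acceleration, extensor-group muscles around intervals of negative
#' elbow acceleration (so the first flexor burst precedes the first
#' extensor burst on a flexion-extension target). Each burst is a smooth
#' Hann bump of width `burst_width_fraction * duration`. Zero-mean
#' Gaussian noise of sd `noise_sd` is added (seeded; the RNG state of the
#' caller is untouched). The MVC trace is a plateau at `mvc_scale` times
#' the signal peak with the same noise model. Tri_med is not included
#' (deep muscle, not recordable by surface EMG).
#'
#' @param target a `target_trajectory`.
#' @param spec a `synthetic_emg_spec`.
#' @return List of class `emg_set` with `time_s`, `signals` (matrix, one
#'   column per recorded muscle), `mvc` (same shape), `sample_rate_hz`.
#' @export
make_synthetic_emg <- function(target, spec = synthetic_emg_spec()) {
  stopifnot(inherits(target, "target_trajectory"),
            inherits(spec, "synthetic_emg_spec"))
  t <- target$time_s
  dt <- t[2] - t[1]
  duration <- t[length(t)] - t[1]
  acc <- c(0, diff(diff(target$elbow_deg)), 0) / dt^2
  burst_centres <- function(mask) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values & r$lengths >= 3
    (t[starts[keep]] + t[ends[keep]]) / 2
  }
  width <- spec$burst_width_fraction * duration
  signal_for <- function(centres) {
    s <- rep(0, length(t))
    for (ct in centres) s <- s + hann_bump(t, ct, width)
    pmin(s, 1)
  }
  flex_sig <- signal_for(burst_centres(acc > 1e-9))
  ext_sig <- signal_for(burst_centres(acc < -1e-9))
  grp <- elbow_groups()
  recorded <- c("Delt_ant", setdiff(c(grp$flexor, grp$extensor), "Tri_med"))
  base <- sapply(recorded, function(m) {
    if (m %in% grp$extensor) ext_sig else flex_sig
  })
  peak <- max(base, 1e-6)
  mvc_base <- matrix(spec$mvc_scale * peak *
                       signal_for(duration / 2),
                     nrow = length(t), ncol = length(recorded),
                     dimnames = list(NULL, recorded))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(spec$seed)
  noise <- function(mat) {
    if (spec$noise_sd == 0) return(mat)
    mat + matrix(stats::rnorm(length(mat), 0, spec$noise_sd), nrow(mat))
  }
  structure(list(time_s = t,
                 signals = noise(base),
                 mvc = noise(mvc_base),
                 sample_rate_hz = 1 / dt),
            class = "emg_set")
}
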