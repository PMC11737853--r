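#' Root mean square error between simulated and target trajectories
#'
#' `sqrt( (mse_shoulder + mse_elbow) / 2 )` in degrees; the target is
#' linearly interpolated onto the simulation time base.
#'
#' @param trace a `simulation_trace`.
#' @param target a `target_trajectory`.
#' @return RMSE in degrees.
#' @export
trajectory_rmse <- function(trace, target) {
  sh_t <- stats::approx(target$time_s, target$shoulder_deg, trace$time_s,
                        rule = 2)$y
  el_t <- stats::approx(target$time_s, target$elbow_deg, trace$time_s,
                        rule = 2)$y
  if (length(sh_t) != length(trace$shoulder_deg))
    stop("length mismatch after interpolation")
  sqrt((mean((trace$shoulder_deg - sh_t)^2) +
        mean((trace$elbow_deg - el_t)^2)) / 2)
}

#' Elbow speed arc length (smoothness)
#'
#' Negative metric, closer to 0 for smoother movements:
#' `-sum_n sqrt(1/N^2 + vhat_n^2)` with the elbow speed normalised by its
#' peak magnitude so the metric is amplitude-invariant. Zero motion gives
#' exactly -1 (only the 1/N terms survive); any speed profile gives a
#' value <= -1.
#'
#' @param speed_deg_s elbow speed series (deg/s), or a `simulation_trace`.
#' @return SAL (dimensionless, <= -1 for N samples summing the 1/N term).
#' @export
elbow_sal <- function(speed_deg_s) {
  if (inherits(speed_deg_s, "simulation_trace"))
    speed_deg_s <- speed_deg_s$elbow_speed_deg_s
  n <- length(speed_deg_s)
  if (n < 2) stop("need at least 2 samples")
  peak <- max(abs(speed_deg_s))
  vhat <- if (peak > 0) speed_deg_s / peak else rep(0, n)
  -sum(sqrt(1 / n^2 + vhat^2))
}

#' Elbow deviation after a perturbation
#'
#' `max_{n >= p} | theta_elb_n - theta_elb_{p-1} |`: the largest absolute
#' excursion of the (perturbed) elbow angle after the perturbation onset,
#' relative to the angle one step before onset. The absolute value makes
#' upward and downward perturbations register alike.
#'
#' @param trace a `simulation_trace` (usually perturbed).
#' @param onset_time_s perturbation onset (s); must lie inside the trace.
#' @return Deviation in degrees.
#' @export
elbow_deviation <- function(trace, onset_time_s) {
  p <- which(trace$time_s >= onset_time_s)[1]
  if (is.na(p) || p < 2)
    stop("perturbation onset outside the trace")
  ref <- trace$elbow_deg[p - 1]
  max(abs(trace$elbow_deg[p:length(trace$elbow_deg)] - ref))
}

# --- Butterworth low-pass design (bilinear transform) -----------------

poly_from_roots <- function(roots) {
  coefs <- 1 + 0i
  for (r in roots) coefs <- c(coefs, 0) - c(0, r * coefs)
  coefs
}

#' Digital Butterworth low-pass filter coefficients
#'
#' Designs an order-n Butterworth low-pass via the analog prototype and
#' the bilinear transform with frequency prewarping (the same construction
#' as scipy.signal.butter / MATLAB butter).
#'
#' @param order filter order.
#' @param cutoff_hz cutoff frequency (Hz).
#' @param fs_hz sampling rate (Hz); must exceed twice the cutoff.
#' @return List with numerator `b` and denominator `a` coefficients.
#' @export
butter_lowpass <- function(order, cutoff_hz, fs_hz) {
  stopifnot(order >= 1, cutoff_hz > 0, fs_hz > 2 * cutoff_hz)
  k <- seq_len(order)
  p_proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  warped <- 2 * fs_hz * tan(pi * cutoff_hz / fs_hz)
  p <- warped * p_proto
  # bilinear transform of poles; zeros all map to z = -1
  pd <- (1 + p / (2 * fs_hz)) / (1 - p / (2 * fs_hz))
  gain <- Re(warped^order / prod(2 * fs_hz - p))
  a <- Re(poly_from_roots(pd))
  b <- gain * Re(poly_from_roots(rep(-1 + 0i, order)))
  list(b = b, a = a)
}

# Direct-form IIR filtering, zero initial conditions.
iir_filter <- function(b, a, x) {
  n <- length(x)
  nb <- length(b); na <- length(a)
  y <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(min(nb, i)))
      acc <- acc + b[j] * x[i - j + 1]
    for (j in 2:na)
      if (i - j + 1 >= 1) acc <- acc - a[j] * y[i - j + 1]
    y[i] <- acc / a[1]
  }
  y
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies the filter forward and backward with odd-reflection edge
#' padding, eliminating phase lag so activation-window timing is not
#' distorted.
#'
#' @param b,a filter coefficients.
#' @param x signal.
#' @return Filtered signal, same length as `x`.
#' @export
filtfilt_zero_phase <- function(b, a, x) {
  n <- length(x)
  padlen <- min(n - 1, 3 * 50 * max(length(a), length(b)))
  pre <- 2 * x[1] - x[seq(padlen + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - padlen)]
  ext <- c(pre, x, post)
  y <- iir_filter(b, a, ext)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(padlen + 1):(padlen + n)]
}

#' EMG envelope: rectify, low-pass, MVC-normalise, resample
#'
#' Rectifies the raw signal, low-pass filters it with a zero-phase
#' 5th-order Butterworth at 5 Hz, divides by the maximum of the
#' identically processed MVC recording, and linearly interpolates onto the
#' requested simulation time points.
#'
#' @param raw_signal raw EMG-like signal.
#' @param fs_hz its sampling rate (Hz), > 10.
#' @param mvc_raw raw MVC signal on the same time base.
#' @param time_s time base of `raw_signal` (s); defaults to a uniform grid
#'   at `fs_hz`.
#' @param out_time_s simulation time points to interpolate onto (default:
#'   the input time base).
#' @param cutoff_hz,order filter settings.
#' @return Normalised envelope at `out_time_s`.
#' @export
emg_envelope <- function(raw_signal, fs_hz, mvc_raw,
                         time_s = (seq_along(raw_signal) - 1) / fs_hz,
                         out_time_s = time_s,
                         cutoff_hz = 5, order = 5) {
  if (fs_hz <= 10) stop("fs_hz must exceed 10 Hz")
  flt <- butter_lowpass(order, cutoff_hz, fs_hz)
  env <- filtfilt_zero_phase(flt$b, flt$a, abs(raw_signal))
  mvc_env <- filtfilt_zero_phase(flt$b, flt$a, abs(mvc_raw))
  mvc_max <- max(mvc_env)
  if (mvc_max <= 0) stop("MVC maximum is zero; cannot normalise")
  stats::approx(time_s, env / mvc_max, out_time_s, rule = 2)$y
}

#' Activation time windows from an envelope
#'
#' A sample is "active" when the envelope exceeds `perc`% of its own RMS
#' value. Default thresholds: 85% for flexor groups, 65% for extensors.
#'
#' @param envelope numeric envelope series.
#' @param perc threshold as percent of the envelope RMS, > 0.
#' @return Logical series.
#' @export
activation_windows <- function(envelope, perc) {
  stopifnot(perc > 0)
  envelope > perc / 100 * sqrt(mean(envelope^2))
}

#' Overlap between EMG and simulated activation windows
#'
#' `100 * ( N_overlap / N_EMG - N_EMG_only / N_tot - N_sim_only / N_tot )`:
#' positive credit for coinciding activity (relative to the EMG window
#' size), negative for activity present in only one of the two series
#' (relative to the full signal length). Identical nonempty windows give
#' 100; an empty EMG window scores minus the lone simulated fraction.
#'
#' @param emg_windows,sim_windows equal-length logical series.
#' @return Overlap in percent (<= 100).
#' @export
window_overlap <- function(emg_windows, sim_windows) {
  stopifnot(length(emg_windows) == length(sim_windows))
  n_tot <- length(emg_windows)
  n_emg <- sum(emg_windows)
  n_overlap <- sum(emg_windows & sim_windows)
  n_emg_only <- sum(emg_windows & !sim_windows)
  n_sim_only <- sum(!emg_windows & sim_windows)
  if (n_emg == 0) return(-100 * n_sim_only / n_tot)
  100 * (n_overlap / n_emg - n_emg_only / n_tot - n_sim_only / n_tot)
}

#' Group-level EMG overlap metrics for a simulation trace
#'
#' Averages the elbow flexor and extensor EMG envelopes and simulated
#' activation signals (the medial triceps is excluded from the simulated
#' extensor mean since it is not surface-recordable), thresholds each mean
#' at its group percentage of RMS (85% flexors, 65% extensors) and
#' computes the per-group and total window overlaps.
#'
#' @param trace a `simulation_trace`.
#' @param emg an `emg_set`.
#' @param perc_flexor,perc_extensor RMS-percentage thresholds.
#' @return List with `overlap_flexor_pct`, `overlap_extensor_pct`,
#'   `overlap_total_pct`.
#' @export
emg_overlap <- function(trace, emg, perc_flexor = 85, perc_extensor = 65) {
  grp <- elbow_groups()
  flex <- grp$flexor
  ext_emg <- intersect(grp$extensor, colnames(emg$signals))
  ext_sim <- setdiff(grp$extensor, "Tri_med")
  env_of <- function(muscle) {
    emg_envelope(emg$signals[, muscle], emg$sample_rate_hz,
                 emg$mvc[, muscle], time_s = emg$time_s,
                 out_time_s = trace$time_s)
  }
  emg_flex <- rowMeans(sapply(flex, env_of))
  emg_ext <- rowMeans(sapply(ext_emg, env_of))
  sim_flex <- rowMeans(trace$a[, flex, drop = FALSE])
  sim_ext <- rowMeans(trace$a[, ext_sim, drop = FALSE])
  ov_f <- window_overlap(activation_windows(emg_flex, perc_flexor),
                         activation_windows(sim_flex, perc_flexor))
  ov_e <- window_overlap(activation_windows(emg_ext, perc_extensor),
                         activation_windows(sim_ext, perc_extensor))
  list(overlap_flexor_pct = ov_f, overlap_extensor_pct = ov_e,
       overlap_total_pct = (ov_f + ov_e) / 2)
}

#' Full metrics report for one trace
#'
#' @param trace a `simulation_trace`.
#' @param target a `target_trajectory`.
#' @param emg optional `emg_set` for overlap metrics.
#' @param perturbation_onset_s optional onset (s) for the deviation
#'   metric.
#' @return List of class `metrics_report`.
#' @export
metrics_report <- function(trace, target, emg = NULL,
                           perturbation_onset_s = NULL) {
  rep <- list(rmse_deg = trajectory_rmse(trace, target),
              sal = elbow_sal(trace))
  if (!is.null(perturbation_onset_s))
    rep$deviation_deg <- elbow_deviation(trace, perturbation_onset_s)
  if (!is.null(emg))
    rep <- c(rep, emg_overlap(trace, emg))
  structure(rep, class = "metrics_report")
}
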