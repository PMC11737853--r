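fake_trace <- function(time_s, shoulder_deg, elbow_deg,
                       a = matrix(0, length(time_s), 7,
                                  dimnames = list(NULL, muscle_names()))) {
  speed <- c(0, diff(elbow_deg) / diff(time_s))
  structure(list(time_s = time_s, shoulder_deg = shoulder_deg,
                 elbow_deg = elbow_deg, elbow_speed_deg_s = speed,
                 a = a), class = "simulation_trace")
}

fake_target <- function(time_s, shoulder_deg, elbow_deg) {
  structure(data.frame(time_s = time_s, shoulder_deg = shoulder_deg,
                       elbow_deg = elbow_deg),
            class = c("target_trajectory", "data.frame"))
}

test_that("RMSE has the closed-form behaviour of the averaged-joint form", {
  t <- seq(0, 1, by = 0.01)
  tgt <- fake_target(t, sin(t) * 10, 20 + 30 * t)
  tr0 <- fake_trace(t, tgt$shoulder_deg, tgt$elbow_deg)
  expect_equal(trajectory_rmse(tr0, tgt), 0)
  # constant offset on both joints -> exactly the offset
  tr1 <- fake_trace(t, tgt$shoulder_deg + 3, tgt$elbow_deg + 3)
  expect_equal(trajectory_rmse(tr1, tgt), 3)
  # offset on the elbow only -> offset / sqrt(2)
  tr2 <- fake_trace(t, tgt$shoulder_deg, tgt$elbow_deg + 3)
  expect_equal(trajectory_rmse(tr2, tgt), 3 / sqrt(2))
})

test_that("RMSE is symmetric and satisfies the triangle inequality", {
  t <- seq(0, 1, by = 0.01)
  a <- fake_trace(t, sin(t), cos(t))
  b <- fake_target(t, 2 * sin(t) + 1, t)
  c3 <- fake_target(t, -t, 3 * cos(t))
  as_target <- function(tr) fake_target(tr$time_s, tr$shoulder_deg,
                                        tr$elbow_deg)
  as_trace <- function(tg) fake_trace(tg$time_s, tg$shoulder_deg,
                                      tg$elbow_deg)
  d_ab <- trajectory_rmse(a, b)
  d_ba <- trajectory_rmse(as_trace(b), as_target(a))
  expect_equal(d_ab, d_ba)
  d_ac <- trajectory_rmse(a, c3)
  d_bc <- trajectory_rmse(as_trace(b), c3)
  expect_lte(d_ac, d_ab + d_bc + 1e-12)
})

test_that("SAL matches hand-evaluated cases and penalises jitter", {
  # zero motion: only the 1/N terms -> exactly -1
  expect_equal(elbow_sal(rep(0, 50)), -1)
  # triangular normalised profile {0, 1, 0}
  expect_equal(elbow_sal(c(0, 5, 0)),
               -(1 / 3 + sqrt(1 / 9 + 1) + 1 / 3))
  # any profile is <= -1
  set.seed(4)
  for (i in 1:5) expect_lte(elbow_sal(rnorm(100)), -1)
  # amplitude invariance via peak normalisation
  v <- sin(seq(0, pi, length.out = 100))
  expect_equal(elbow_sal(v), elbow_sal(10 * v))
  # jitter makes SAL more negative (20 seeded draws). The per-sample
  # form sums |vhat|, so the property holds as long as the jitter does
  # not raise the normalising peak: keep the peak region clean.
  clean <- 100 * sin(seq(0, pi, length.out = 200))^2
  s0 <- elbow_sal(clean)
  set.seed(11)
  for (i in 1:20) {
    jit <- clean + pmin(abs(rnorm(200, 0, 10)), 19) * (clean < 80)
    expect_lte(max(abs(jit)), max(abs(clean)))
    expect_lte(elbow_sal(jit), s0 + 1e-9)
  }
})

test_that("deviation is the post-onset excursion from the pre-onset sample", {
  t <- seq(0, 1, by = 0.01)
  # instantaneous +10 deg offset after onset, otherwise flat
  elb <- ifelse(t >= 0.5, 30, 20)
  tr <- fake_trace(t, rep(0, length(t)), elb)
  expect_equal(elbow_deviation(tr, 0.5), 10)
  # sign flip of the excursion leaves deviation unchanged
  tr2 <- fake_trace(t, rep(0, length(t)), ifelse(t >= 0.5, 10, 20))
  expect_equal(elbow_deviation(tr2, 0.5), 10)
  # null case: deviation equals the natural excursion from the reference
  tr3 <- fake_trace(t, rep(0, length(t)), 20 + 10 * t)
  expect_equal(elbow_deviation(tr3, 0.5), 20 + 10 * 1 - (20 + 10 * 0.49))
  expect_error(elbow_deviation(tr3, 5), "onset")
})

test_that("Butterworth design matches the reference implementation", {
  # frozen coefficients from scipy.signal.butter(5, 5, fs=1000) and
  # butter(5, 5, fs=200)
  f1 <- butter_lowpass(5, 5, 1000)
  expect_equal(f1$b,
    c(9.092866114819e-10, 4.546433057410e-09, 9.092866114819e-09,
      9.092866114819e-09, 4.546433057410e-09, 9.092866114819e-10),
    tolerance = 1e-9)
  expect_equal(f1$a,
    c(1, -4.898337145712, 9.598497090806, -9.405307989196,
      4.608476358537, -0.903328285338), tolerance = 1e-9)
  f2 <- butter_lowpass(5, 5, 200)
  expect_equal(f2$a,
    c(1, -4.491830965077, 8.094055417827, -7.312081280150,
      3.311047561988, -0.601115822860), tolerance = 1e-9)
  # DC gain is one
  expect_equal(sum(f1$b) / sum(f1$a), 1, tolerance = 1e-6)
})

test_that("EMG envelope has unit DC gain and rectified-mean response", {
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)
  # constant signal with MVC at the same level -> envelope ~ 1
  env <- emg_envelope(rep(0.5, length(t)), fs, rep(0.5, length(t)))
  mid <- env[t > 0.5 & t < 1.5]
  expect_equal(mean(mid), 1, tolerance = 1e-3)
  # 50 Hz sinusoid: envelope ~ rectified mean 2/pi * A (before MVC scale)
  amp <- 0.8
  x <- amp * sin(2 * pi * 50 * t)
  mvc <- rep(amp, length(t))     # MVC processes to ~ amp
  env2 <- emg_envelope(x, fs, mvc)
  mid2 <- env2[t > 0.5 & t < 1.5]
  expect_equal(mean(mid2), 2 / pi, tolerance = 0.02)
  expect_lt((max(mid2) - min(mid2)) / mean(mid2), 0.05)  # ripple < 5%
  # scaling raw and MVC together leaves the envelope unchanged
  env3 <- emg_envelope(3 * x, fs, 3 * mvc)
  expect_lt(max(abs(env3 - env2)), 1e-6)
  expect_error(emg_envelope(x, fs, rep(0, length(t))), "MVC")
})

test_that("activation windows threshold at perc % of RMS", {
  expect_true(all(activation_windows(rep(0.7, 100), 85)))
  expect_false(any(activation_windows(rep(0, 100), 85)))
  # half-sine at perc 100: active where sin > 1/sqrt(2), the central half
  x <- sin(seq(0, pi, length.out = 1001))
  w <- activation_windows(x, 100)
  expect_equal(mean(w), 0.5, tolerance = 0.01)
})

test_that("window overlap matches the counted form", {
  n <- 100
  w <- rep(FALSE, n)
  a <- w; a[26:50] <- TRUE
  # identical nonempty windows -> 100
  expect_equal(window_overlap(a, a), 100)
  # disjoint windows of 25% coverage each -> -50
  b <- w; b[51:75] <- TRUE
  expect_equal(window_overlap(a, b), -50)
  # sim everywhere, EMG on half -> 100 * (1 - 0 - 0.5) = 50
  half <- w; half[1:50] <- TRUE
  expect_equal(window_overlap(half, rep(TRUE, n)), 50)
  # empty EMG window: minus the lone simulated fraction
  expect_equal(window_overlap(w, a), -25)
  # never exceeds 100; 100 iff identical and nonempty
  set.seed(2)
  for (i in 1:20) {
    e <- runif(n) > 0.6; s <- runif(n) > 0.6
    ov <- window_overlap(e, s)
    expect_lte(ov, 100)
    if (ov == 100) expect_identical(e, s)
  }
})

test_that("group overlap pipeline runs on synthetic EMG", {
  tgt <- make_target()
  emg <- make_synthetic_emg(tgt, synthetic_emg_spec(noise_sd = 0.02))
  cfg <- simulation_config(target = tgt,
                           commands = command_set_from_vector(
                             c(0.4, 0.36, 0, 0.02, 0.3, 0.36, pi, 0.02)))
  tr <- run_simulation(cfg)
  ov <- emg_overlap(tr, emg)
  expect_true(is.finite(ov$overlap_total_pct))
  expect_lte(ov$overlap_total_pct, 100)
  expect_equal(ov$overlap_total_pct,
               (ov$overlap_flexor_pct + ov$overlap_extensor_pct) / 2)
  rep <- metrics_report(tr, tgt, emg = emg)
  expect_true(all(c("rmse_deg", "sal", "overlap_total_pct") %in%
                  names(rep)))
  expect_lte(rep$sal, -1)
})
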