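test_that("muscle roster and relations match the seven-muscle arm", {
  expect_identical(muscle_names(),
                   c("Delt_ant", "Tri_long", "Tri_lat", "Tri_med",
                     "Bic_long", "Bic_short", "Brach"))
  rel <- muscle_relations()
  expect_true(isSymmetric(rel$antagonist_matrix))
  expect_true(isSymmetric(rel$synergist_matrix))
  expect_false(any(rel$antagonist_matrix & rel$synergist_matrix))
  expect_equal(nrow(rel$antagonists), 6)
  expect_equal(nrow(rel$synergists), 7)
})

test_that("muscle parameter invariants hold and are enforced", {
  p <- default_muscle_parameters()
  expect_silent(reflexarm:::validate_muscle_parameters(p))
  bad <- p
  bad$moment_arm_elbow_mm[bad$name == "Delt_ant"] <- 5
  expect_error(reflexarm:::validate_muscle_parameters(bad), "Delt_ant")
  bad2 <- p
  bad2$moment_arm_shoulder_mm[bad2$name == "Bic_long"] <- 0
  expect_error(reflexarm:::validate_muscle_parameters(bad2), "biarticular")
})

test_that("muscle geometry is the linear constant-moment-arm map", {
  p <- default_muscle_parameters()
  ref <- attr(p, "reference_posture_deg") * pi / 180
  g0 <- muscle_geometry(ref[["shoulder"]], ref[["elbow"]], params = p)
  expect_equal(unname(g0$length_mm), p$reference_length_mm)
  # elbow flexion by 0.5 rad shortens Brach (20 mm arm) by 10 mm
  g1 <- muscle_geometry(ref[["shoulder"]], ref[["elbow"]] + 0.5, params = p)
  expect_equal(g1$length_mm[["Brach"]], g0$length_mm[["Brach"]] - 10)
  # Delt_ant unaffected by pure elbow motion
  expect_equal(g1$length_mm[["Delt_ant"]], g0$length_mm[["Delt_ant"]])
  # velocity by the chain rule
  g2 <- muscle_geometry(ref[["shoulder"]], ref[["elbow"]],
                        thetadot_elbow_rad = 2, params = p)
  expect_equal(g2$velocity_mm_s[["Brach"]], -40)
  expect_equal(g2$velocity_mm_s[["Tri_lat"]], 40)
  # floor at half optimal length
  g3 <- muscle_geometry(ref[["shoulder"]], ref[["elbow"]] + 50, params = p)
  expect_true(all(g3$length_mm >= 0.5 * p$optimal_fiber_length_mm))
})

test_that("Hill force matches its closed-form curves", {
  p <- default_muscle_parameters()
  l0 <- p$optimal_fiber_length_mm
  # no drive, optimal length: zero force
  expect_equal(unname(hill_force(0, l0, rep(0, 7), p)), rep(0, 7))
  # full drive, isometric at optimum: F_max (pennation zero)
  expect_equal(unname(hill_force(1, l0, rep(0, 7), p)), p$f_max_n)
  # a = 1, ltilde = 1.2, isometric: hand-evaluated Gaussian + passive
  lt <- 1.2
  expected <- p$f_max_n *
    (exp(-((lt - 1) / 0.45)^2) + (exp(5 * (lt - 1)) - 1) / (exp(2.5) - 1))
  expect_equal(unname(hill_force(1, lt * l0, rep(0, 7), p)), expected)
  # forces are never negative, even at fast shortening
  f <- hill_force(1, 0.9 * l0, -20 * l0, p)
  expect_true(all(f >= 0))
  expect_error(hill_force(-0.1, l0, rep(0, 7), p), "activation")
  expect_error(hill_force(0.5, -l0, rep(0, 7), p), "length")
})

test_that("activation dynamics are exact first-order responses", {
  # fixed point
  expect_equal(activation_step(0.4, 0.4, 0.001), 0.4)
  # rise reaches 1 - exp(-1) after one tau_act, regardless of dt
  a <- 0
  for (i in 1:10) a <- activation_step(a, 1, 0.001, tau_act = 0.010)
  expect_equal(a, 1 - exp(-1), tolerance = 1e-9)
  # deactivation is slower than activation
  a_fall <- 1
  for (i in 1:10) a_fall <- activation_step(a_fall, 0, 0.001)
  expect_gt(a_fall, 1 - a)   # decayed less than the rise gained
  expect_true(all(activation_step(c(0, 1), c(1, 0), 0.5) >= 0))
})
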