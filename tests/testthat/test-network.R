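test_that("sigmoid is increasing with the documented fixed points", {
  expect_equal(neuron_sigmoid(0.5), 0.5)
  expect_equal(neuron_sigmoid(1), 1 / (1 + exp(-4)))
  expect_equal(neuron_sigmoid(0), 1 / (1 + exp(4)))
  expect_lt(neuron_sigmoid(-100), 1e-10)
  expect_gt(neuron_sigmoid(100), 1 - 1e-10)
  x <- seq(-2, 3, by = 0.1)
  expect_true(all(diff(neuron_sigmoid(x)) > 0))
})

test_that("leaky neuron converges to the sigmoid of its input", {
  p <- default_neuron_parameters()
  r <- 0
  for (i in 1:20) r <- neuron_step(r, 0.8, 0.001, p)   # 20 tau
  expect_equal(r, neuron_sigmoid(0.8), tolerance = 1e-3)
  r0 <- 0.5
  for (i in 1:20) r0 <- neuron_step(r0, 0, 0.001, p)
  expect_equal(r0, 1 / (1 + exp(4)), tolerance = 1e-3)
  # step response covers 1 - exp(-1) of its change after one tau
  r1 <- neuron_step(0, 1, 0.001, p)
  target <- neuron_sigmoid(1)
  expect_equal(r1 / target, 1 - exp(-1), tolerance = 1e-9)
})

test_that("network wiring enumerates all 21 muscle pairs correctly", {
  rel <- muscle_relations()
  nm <- muscle_names()
  # expected relation for every unordered pair: "a"ntagonist,
  # "s"ynergist or "-" (none)
  expected <- matrix("-", 7, 7, dimnames = list(nm, nm))
  set_rel <- function(m1, m2, v) {
    expected[m1, m2] <<- v; expected[m2, m1] <<- v
  }
  set_rel("Delt_ant", "Tri_long", "a")
  set_rel("Delt_ant", "Bic_long", "s")
  set_rel("Tri_long", "Tri_lat", "s")
  set_rel("Tri_long", "Tri_med", "s")
  set_rel("Tri_long", "Bic_long", "a")
  set_rel("Tri_lat", "Tri_med", "s")
  set_rel("Tri_lat", "Bic_short", "a")
  set_rel("Tri_lat", "Brach", "a")
  set_rel("Tri_med", "Bic_short", "a")
  set_rel("Tri_med", "Brach", "a")
  set_rel("Bic_long", "Bic_short", "s")
  set_rel("Bic_long", "Brach", "s")
  set_rel("Bic_short", "Brach", "s")
  for (i in 1:6) for (j in (i + 1):7) {
    m1 <- nm[i]; m2 <- nm[j]
    expect_equal(rel$antagonist_matrix[m1, m2], expected[m1, m2] == "a",
                 info = paste(m1, m2))
    expect_equal(rel$synergist_matrix[m1, m2], expected[m1, m2] == "s",
                 info = paste(m1, m2))
  }
})

test_that("build_network wires pathways as specified", {
  net <- build_network(synaptic_weights(IaMN = 0.7, IaINa = 0.4,
                                        IaMNs = 0.6, II = 0.3,
                                        Ib = 0.2, RN = 0.1))
  expect_equal(unname(net$w_iamn), rep(0.7, 7))
  # Tri_lat: antagonist inhibition sources {Bic_short, Brach}
  src <- names(which(net$m_iaina["Tri_lat", ] > 0))
  expect_setequal(src, c("Bic_short", "Brach"))
  expect_equal(unname(net$m_iaina["Tri_lat", src]), c(0.4, 0.4))
  # Tri_lat heteronymous sources {Tri_long, Tri_med}, each w/2
  het <- names(which(net$m_iamns["Tri_lat", ] > 0))
  expect_setequal(het, c("Tri_long", "Tri_med"))
  expect_equal(unname(net$m_iamns["Tri_lat", het]), c(0.3, 0.3))
  # Brach: synergists {Bic_long, Bic_short}, each w/2
  expect_equal(unname(net$m_iamns["Brach", c("Bic_long", "Bic_short")]),
               c(0.3, 0.3))
  # Delt_ant has one synergist: full weight
  expect_equal(unname(net$m_iamns["Delt_ant", "Bic_long"]), 0.6)
  expect_error(synaptic_weights(IaXX = 1), "unknown pathway")
  expect_error(synaptic_weights(IaMN = 1.2, max_weight = 1), "\\[0, 1\\]")
})

test_that("motoneurons isolate to their supraspinal command when weights are 0", {
  net <- build_network(synaptic_weights())
  st <- network_state_init()
  cmd <- c(0, 0, 0, 0, 1, 0, 0)    # drive Bic_long only
  ia <- ii <- ib <- rep(0.3, 7)    # afferents present but disconnected
  for (i in 1:100) {
    out <- network_step(st, net, ia, ii, ib, cmd, 0.001)
    st <- out$state
  }
  expect_equal(unname(out$u[5]), neuron_sigmoid(1), tolerance = 1e-3)
  expect_equal(unname(out$u[1]), neuron_sigmoid(0), tolerance = 1e-3)
})

test_that("reciprocal inhibition lowers antagonist motoneuron rates", {
  net <- build_network(synaptic_weights(IaINa = 1))
  quiet <- rep(0, 7)
  run_net <- function(ia) {
    st <- network_state_init()
    for (i in 1:100) {
      out <- network_step(st, net, ia, quiet, quiet, quiet, 0.001)
      st <- out$state
    }
    out$u
  }
  base <- run_net(rep(0, 7))
  # strong flexor (Brach) Ia input inhibits its antagonists Tri_lat/Tri_med
  stretched <- rep(0, 7); stretched[7] <- 1
  u <- run_net(stretched)
  expect_lt(u[3], base[3])
  expect_lt(u[4], base[4])
  # non-antagonists unaffected
  expect_equal(u[1], base[1], tolerance = 1e-9)
})

test_that("rates stay in [0, 1] for arbitrary bounded inputs", {
  net <- build_network(synaptic_weights(IaMN = 1, IaINa = 1, IaMNs = 1,
                                        II = 1, Ib = 1, RN = 1))
  st <- network_state_init()
  set.seed(9)
  for (i in 1:200) {
    out <- network_step(st, net, runif(7), runif(7), runif(7), runif(7),
                        0.001)
    st <- out$state
    rates <- unlist(st)
    expect_true(all(rates >= 0 & rates <= 1))
  }
})

test_that("removing a pathway recovers superposition at the input sum", {
  # with all weights zero the motoneuron input is exactly the command:
  # adding then removing IaMN leaves the steady state unchanged
  w0 <- synaptic_weights()
  w1 <- synaptic_weights(IaMN = 0.5)
  w1["IaMN", ] <- 0
  expect_equal(unclass(build_network(w1)$w_iamn),
               unclass(build_network(w0)$w_iamn))
})
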