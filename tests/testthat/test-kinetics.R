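test_that("hill_rate matches its closed form and limits", {
  expect_identical(hill_rate(0, k = 10, phi_m = 1e17, exponent = 1), 0)
  # half-saturation by construction, any k / exponent
  for (k in c(1, 18.5)) for (e in c(0.7, 1, 1.45))
    expect_equal(hill_rate(5.07e17, k, 5.07e17, e), k / 2)
  # frozen regression value (direct evaluation of the saturating form)
  expect_equal(hill_rate(2.21e15, 18.5, 5.07e17, 0.982),
               0.0885043194778, tolerance = 1e-10)
  # monotone non-decreasing in phi and bounded by k + baseline
  phis <- 10^seq(12, 22, length.out = 50)
  r <- hill_rate(phis, 18.5, 5.07e17, 0.982, baseline = 0.03)
  expect_true(all(diff(r) >= 0))
  expect_true(all(r <= 18.5 + 0.03))
  expect_error(hill_rate(-1, 1, 1, 1), "non-negative")
})

test_that("transition_rates reproduces the dark, saturation and
           half-saturation limits", {
  p6 <- chr2_params(6); p3 <- chr2_params(3); p4 <- chr2_params(4)
  dark <- transition_rates(p6, 0)
  expect_identical(dark$Ga1, 0)
  expect_identical(dark$Ga2, 0)
  expect_equal(dark$Gf, p6$Gf0)
  expect_equal(dark$Gb, p6$Gb0)
  sat <- transition_rates(p3, 1e30)
  expect_equal(sat$Ga, p3$ka, tolerance = 1e-9)
  expect_equal(sat$Gr, p3$kr + p3$Gr0, tolerance = 1e-9)
  half <- transition_rates(p4, p4$phi_m)
  expect_equal(half$Ga1, p4$k1 / 2)
  expect_equal(half$Gf, p4$kf / 2 + p4$Gf0)
})

test_that("ode_rhs conserves occupancy and has the expected fixed points", {
  p6 <- chr2_params(6)
  # dark ground state is a fixed point
  expect_equal(ode_rhs(ground_state(6), transition_rates(p6, 0)),
               setNames(rep(0, 6), state_names(6)))
  # derivative sum is zero for random states and fluxes
  set.seed(42)
  for (i in 1:20) {
    s <- stats::runif(6); s <- s / sum(s)
    phi <- 10^stats::runif(1, 14, 19)
    expect_equal(sum(ode_rhs(s, transition_rates(p6, phi))), 0,
                 tolerance = 1e-12)
  }
  # symmetric 3-state fixed point
  r <- list(model_order = 3L, Ga = 1, Gd = 1, Gr = 1)
  expect_equal(unname(ode_rhs(rep(1 / 3, 3), r)), rep(0, 3),
               tolerance = 1e-15)
})

test_that("steady_state solves the rate-matrix null space", {
  # symmetric 3-state cycle: all rates 1 at phi = phi_m
  p <- opsin_params(3, g0 = 1e4, phi_m = 1e17, ka = 2, kr = 1.8,
                    p = 1, q = 1, Gd = 1, Gr0 = 0.1, E = 0, v0 = 43)
  ss <- steady_state(p, 1e17)   # Ga = 1, Gd = 1, Gr = 0.9 + 0.1 = 1
  expect_equal(unname(ss), rep(1 / 3, 3), tolerance = 1e-12)
  # dark fixed point for every model order
  for (n in c(3, 4, 6)) {
    ss0 <- steady_state(chr2_params(n), 0)
    expect_equal(unname(ss0[1]), 1, tolerance = 1e-12)
  }
  # 6-state steady state equals the long-time limit of integration
  p6 <- chr2_params(6)
  phi <- 2.21e15
  ss6 <- steady_state(p6, phi)
  stim <- light_stimulus(30000, list(pulse_segment(0, 30000, phi)))
  S <- simulate_states(p6, stim, times = c(0, 30000))
  expect_lt(max(abs(S[2, ] - ss6)), 1e-6)
})

test_that("the analytic 3-state solution matches the stiff ODE oracle", {
  p3 <- chr2_params(3)
  tms <- seq(0, 500, by = 0.5)
  a <- analytic_three_state(p3, 2.65e17, times = tms)
  expect_false(attr(a, "degenerate"))
  expect_equal(unname(a[1, 2:4]), c(1, 0, 0))   # t = 0 -> state0
  stim <- light_stimulus(500, list(pulse_segment(0, 500, 2.65e17)))
  S <- simulate_states(p3, stim, tms, method = "lsoda",
                       rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(a[, 2:4] - S)), 1e-6)
  # dark start stays put
  a0 <- analytic_three_state(p3, 0, times = c(0, 100, 400))
  expect_equal(unname(a0[, "C"]), rep(1, 3), tolerance = 1e-12)
})

test_that("photocycle and voltage conductance factors are correct", {
  expect_identical(f_phi(c(1, 0, 0)), 0)
  expect_equal(f_phi(c(0.3, 0.5, 0.2, 0), gamma = 0.05), 0.51)
  s6 <- c(0, 0, 0.4, 0.3, 0, 0.3)
  expect_identical(f_phi(s6, gamma = 0), 0.4)
  # normalization at -70 mV
  expect_equal(f_v(-70, 0, 43, v1_from_constraint(0, 43)), 1,
               tolerance = 1e-9)
  # analytic limit at v = E
  expect_equal(f_v(0, 0, 43, 17.1), 17.1 / 43, tolerance = 1e-9)
  # continuity across the series switch threshold
  v0 <- 43; eps <- 1e-3 * v0
  for (u in c(eps * (1 - 1e-9), eps * (1 + 1e-9)))
    expect_equal(f_v(u, 0, v0, 17.1), f_v(eps, 0, v0, 17.1),
                 tolerance = 1e-9)
  # large v0: linear (non-rectifying) regime, f_v ~ v1/v0
  cc <- 0.75
  vals <- f_v(seq(-100, 80, by = 20), 0, 1e6, 1e6 * cc)
  expect_equal(vals, rep(cc, length(vals)), tolerance = 1e-4)
})

test_that("the current equation applies the conductance factorization", {
  p6 <- chr2_params(6)
  # f_phi = 0 gives zero current at any voltage
  expect_identical(photocurrent_of_state(p6, ground_state(6), -100), 0)
  # direct unit arithmetic: g0 = 2.76e4 pS, f_phi = f_v = 1 at -70 mV
  s <- c(0, 0, 1, 0, 0, 0)  # O1 = 1
  expect_equal(photocurrent_of_state(p6, s, -70), -1.932,
               tolerance = 1e-9)
  # v = E gives zero current (f_v finite)
  expect_equal(photocurrent_of_state(p6, s, p6$E), 0)
})
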