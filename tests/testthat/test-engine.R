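test_that("the output time-step follows the shortest stimulation feature", {
  sp <- make_protocol("shortPulse", list(durations = 1, delay = 100,
                                         tail = 100))
  expect_equal(choose_dt(sp), 0.1)
  sp2 <- make_protocol("shortPulse", list(durations = 0.005))
  expect_equal(choose_dt(sp2), 1e-3)            # floor
  st <- make_protocol("step")                   # all features >= 10 ms
  expect_equal(choose_dt(st), 0.1)              # ceiling
})

test_that("darkness yields an identically zero current", {
  p6 <- chr2_params(6)
  stim <- light_stimulus(200, list())
  pc <- simulate_photocurrent(p6, stim, v = -70, dt = 0.1)
  expect_identical(max(abs(pc$I)), 0)
})

test_that("terminal occupancy of a long pulse matches the steady state", {
  p3 <- chr2_params(3)
  phi <- 1e17
  stim <- light_stimulus(3000, list(pulse_segment(0, 3000, phi)))
  pc <- simulate_photocurrent(p3, stim, v = -70, dt = 0.1)
  expect_lt(max(abs(pc$states[nrow(pc$states), ] - steady_state(p3, phi))),
            1e-6)
})

test_that("analytic propagation agrees with the adaptive stiff solver", {
  tms <- seq(0, 400, by = 0.2)
  for (n in c(3, 6)) {
    p <- chr2_params(n)
    stim <- light_stimulus(400, list(pulse_segment(25, 250, 2.65e17)))
    Sa <- simulate_states(p, stim, tms, method = "auto")
    Sl <- simulate_states(p, stim, tms, method = "lsoda")
    expect_lt(max(abs(Sa - Sl)), 1e-6)
  }
})

test_that("trajectories conserve occupancy and stay in [0, 1]", {
  p6 <- chr2_params(6)
  specs <- list(make_protocol("step", list(fluxes = 2.65e17, on_dur = 200,
                                           tail = 200)),
                make_protocol("shortPulse", list(durations = c(1, 5))),
                make_protocol("sinusoid", list(on_dur = 200, tail = 100)))
  for (spec in specs) {
    pd <- run_protocol(p6, spec)
    for (pc in pd$trials) {
      expect_lt(max(abs(rowSums(pc$states) - 1)), 1e-6)
      expect_true(all(pc$states > -1e-6 & pc$states < 1 + 1e-6))
    }
  }
})

test_that("run_protocol produces one annotated trace per grid point", {
  p6 <- chr2_params(6)
  rect <- run_protocol(p6, make_protocol("rectifier",
                                         list(on_dur = 300, tail = 100)))
  expect_length(rect$trials, 7)
  expect_setequal(rect$index$V, c(-100, -70, -40, -10, 20, 50, 80))
  fl <- 10^seq(log10(2.21e15), log10(2.65e17), length.out = 6)
  st <- run_protocol(p6, make_protocol("step", list(fluxes = fl,
                                                    on_dur = 200,
                                                    tail = 100)))
  expect_length(st$trials, 6)
  rec <- run_protocol(chr2_params(3),
                      make_protocol("recovery", list(on_dur = 100,
                                                     tail = 100)))
  expect_length(rec$trials, 5)
  expect_true(all(vapply(rec$trials, function(pc) nrow(pc$pulses),
                         integer(1)) == 2L))
})

test_that("4- and 6-state models agree for long pulses and differ in
           peak timing for short ones", {
  p4 <- chr2_params(4); p6 <- chr2_params(6)
  # long-pulse equivalence: the 4-state scheme is the fast-activation
  # limit of the 6-state one
  p6fast <- p6; p6fast$Go1 <- 200; p6fast$Go2 <- 200
  stim <- light_stimulus(450, list(pulse_segment(25, 275, 2.65e17)))
  pk4 <- find_peak(simulate_photocurrent(p4, stim, dt = 0.05))
  pk6 <- find_peak(simulate_photocurrent(p6fast, stim, dt = 0.05))
  expect_lt(abs(abs(pk4$value) - abs(pk6$value)) / abs(pk4$value), 0.02)
  # short sub-saturating pulses: 4-state peaks at the pulse end, 6-state
  # strictly after, with the lag shrinking as the pulse lengthens
  phi <- make_protocol("shortPulse")$fluxes
  durations <- c(0.5, 1, 2, 3, 5)
  lags6 <- numeric(0)
  for (w in durations) {
    stim_w <- light_stimulus(10 + w + 150,
                             list(pulse_segment(10, 10 + w, phi)))
    pc4 <- simulate_photocurrent(p4, stim_w, dt = 0.02)
    pc6 <- simulate_photocurrent(p6, stim_w, dt = 0.02)
    expect_lt(abs(find_peak(pc4)$time - (10 + w)), 0.02 + 1e-9)
    lag6 <- find_peak(pc6)$time - (10 + w)
    expect_gt(lag6, 0)
    lags6 <- c(lags6, lag6)
  }
  expect_true(all(diff(lags6) <= 1e-9))
})

test_that("NMODL and network-equation exports are structural and
           deterministic", {
  p6 <- chr2_params(6)
  txt <- emit_nmodl(p6)
  expect_match(txt, "STATE \\{ C1 I1 O1 O2 I2 C2 \\}")
  expect_match(txt, "k1 = 18.5", fixed = TRUE)
  expect_match(txt, "Gr0 = 0.00033", fixed = TRUE)
  expect_match(txt, "DERIVATIVE states")
  expect_identical(txt, emit_nmodl(chr2_params(6)))   # byte-identical
  txt3 <- emit_nmodl(chr2_params(3))
  expect_match(txt3, "STATE \\{ C O D \\}")
  net <- emit_network_equations(p6)
  expect_match(net, "dC1/dt", fixed = TRUE)
  expect_match(net, "fphi = O1 + gamma * O2", fixed = TRUE)
  expect_identical(net, emit_network_equations(chr2_params(6)))
})
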