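make_pc <- function(I, dt = 1, pulses = matrix(c(10, 60), 1), phi = 1e16,
                    V = -70)
  photocurrent(I = I, t = dt, pulses = pulses, phi = phi, V = V)

test_that("photocurrent construction validates its annotations", {
  pc <- make_pc(rep(0, 101))
  expect_equal(pc$t[2] - pc$t[1], 1)
  expect_error(photocurrent(I = 1:5, t = 1:4, pulses = matrix(c(1, 2), 1),
                            phi = 1, V = -70), "same length")
  expect_error(photocurrent(I = 1:5, t = c(0, 1, 1, 2, 3),
                            pulses = matrix(c(1, 2), 1), phi = 1, V = -70),
               "strictly increasing")
  expect_error(make_pc(rep(0, 101), pulses = matrix(c(50, 200), 1)),
               "inside the recorded interval")
})

test_that("find_peak keeps the sign and resolves ties to the earliest
           sample", {
  # monotone-saturating on-phase: peak at the last on-sample
  I <- c(rep(0, 10), -(1 - exp(-(0:50) / 10)), rep(-0.6, 40))
  pc <- make_pc(I)
  pk <- find_peak(pc)
  expect_equal(pk$time, 60)
  expect_lt(pk$value, 0)
  # tie -> earliest
  I2 <- c(rep(0, 10), -1, -0.5, -1, rep(0, 88))
  pk2 <- find_peak(make_pc(I2))
  expect_equal(pk2$time, 10)
  expect_error(find_peak(photocurrent(I = 1:3, t = 1,
                                      pulses = matrix(numeric(0), 0, 2),
                                      phi = 1, V = -70)), "no pulses")
})

test_that("peak timing of simulated short pulses matches the model class", {
  phi <- 2.65e17
  stim <- light_stimulus(100, list(pulse_segment(10, 11, phi)))
  pc4 <- simulate_photocurrent(chr2_params(4), stim, dt = 0.02)
  expect_equal(find_peak(pc4)$time, 11, tolerance = 0.03)
  pc6 <- simulate_photocurrent(chr2_params(6), stim, dt = 0.02)
  expect_gt(find_peak(pc6)$time, 11)
})

test_that("the plateau detector accepts flat tails and flags ramps", {
  flat <- make_pc(c(rep(0, 10), rep(-0.8, 50), rep(0, 41)))
  ss <- find_steady_state(flat)
  expect_true(ss$at_plateau)
  expect_equal(ss$value, -0.8)
  ramp <- make_pc(c(rep(0, 10), seq(0, -1, length.out = 50), rep(0, 41)))
  expect_false(find_steady_state(ramp)$at_plateau)
  # too-short on-phase
  short <- make_pc(rep(-1, 101), pulses = matrix(c(10, 30), 1))
  expect_false(find_steady_state(short)$at_plateau)
  # simulated 3-state long pulse matches the closed-form steady state
  p3 <- chr2_params(3)
  phi <- 1e17
  stim <- light_stimulus(900, list(pulse_segment(25, 625, phi)))
  pc <- simulate_photocurrent(p3, stim, v = -70, dt = 0.1)
  ss3 <- find_steady_state(pc)
  I_pred <- photocurrent_of_state(p3, steady_state(p3, phi), -70)
  expect_true(ss3$at_plateau)
  expect_lt(abs(ss3$value - I_pred) / abs(I_pred), 0.005)
})

test_that("phase segmentation partitions the post-onset trace", {
  cases <- list(
    matrix(c(10, 60), 1, byrow = TRUE),
    matrix(c(10, 30, 50, 70), 2, byrow = TRUE),
    matrix(c(10, 100), 1, byrow = TRUE))  # pulse ending at trace end
  for (pulses in cases) {
    pc <- make_pc(rep(-1, 101), pulses = pulses)
    ph <- segment_phases(pc)
    all_idx <- sort(unname(unlist(ph)))
    expect_identical(all_idx, which(pc$t >= pulses[1, 1]))
    expect_identical(anyDuplicated(all_idx), 0L)
  }
})

test_that("recovery peaks align to the first pulse offset", {
  mk <- function(ipi, peak2) {
    n <- 200 + ipi
    I <- rep(0, n + 1); t <- 0:n
    on2 <- 100 + ipi
    I[t >= 10 & t < 60] <- -1
    I[t >= on2 & t < on2 + 50] <- peak2
    photocurrent(I = I, t = 1,
                 pulses = matrix(c(10, 60, on2, on2 + 50), 2, byrow = TRUE),
                 phi = 1e16, V = -70)
  }
  pd <- protocol_data("recovery", n_runs = 3, phis = 1e16, Vs = -70)
  peaks <- c(-1.2, -1.5, -1.9)
  ipis <- c(100, 200, 400)
  for (i in 1:3) pd <- add_trial(pd, mk(ipis[i], peaks[i]), run = i)
  al <- align_peaks_to_first_offset(pd)
  expect_equal(al$I_p, peaks)
  expect_equal(al$t_p, 100 + ipis - 60)
  expect_true(all(diff(al$t_p) > 0))   # IPI ordering preserved
  bad <- protocol_data("recovery", n_runs = 1, phis = 1e16, Vs = -70)
  bad <- add_trial(bad, make_pc(rep(0, 101)), run = 1)
  expect_error(align_peaks_to_first_offset(bad), ">= 2 pulses")
})

test_that("CSV + manifest round-trip preserves traces and features", {
  p6 <- chr2_params(6)
  spec <- make_protocol("step", list(fluxes = c(1e16, 1e17), on_dur = 100,
                                     tail = 100))
  pd <- run_protocol(p6, spec)
  dir <- tempfile()
  write_protocol_data(pd, dir)
  back <- read_protocol_data(dir)
  expect_identical(length(back$trials), length(pd$trials))
  for (i in seq_along(pd$trials)) {
    expect_identical(back$trials[[i]]$I, pd$trials[[i]]$I)
    expect_identical(back$trials[[i]]$t, pd$trials[[i]]$t)
    # recomputed features identical after the round trip
    expect_identical(find_peak(back$trials[[i]]),
                     find_peak(pd$trials[[i]]))
    expect_identical(find_steady_state(back$trials[[i]]),
                     find_steady_state(pd$trials[[i]]))
  }
  unlink(dir, recursive = TRUE)
})
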