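test_that("preconfigured protocols carry the standard defaults", {
  rect <- make_protocol("rectifier")
  expect_identical(rect$voltages, c(-100, -70, -40, -10, 20, 50, 80))
  expect_length(rect$fluxes, 1)
  rec <- make_protocol("recovery")
  expect_identical(rec$ipis, c(500, 1000, 2500, 5000, 10000))
  expect_identical(rec$runs, 5L)
  sp <- make_protocol("shortPulse")
  expect_identical(sp$durations, c(0.5, 1, 2, 3, 5, 8, 10))
  # step fluxes are the mW/mm^2 series converted to photon flux at 470 nm
  st <- make_protocol("step")
  expect_equal(st$fluxes, irradiance_to_flux(c(0.1, 0.5, 1, 5, 10, 50, 100)))
  # override path
  one <- make_protocol("step", list(fluxes = 1e16))
  expect_identical(one$fluxes, 1e16)
  expect_error(make_protocol("squiggle"), "unknown protocol")
  expect_error(make_protocol("step", list(nonsense = 1)), "invalid override")
  expect_error(make_protocol("recovery", list(ipis = 500)), ">= 2 IPIs")
})

test_that("irradiance converts through the photon energy at 470 nm", {
  expect_equal(irradiance_to_flux(1), 2.36603e15, tolerance = 1e-5)
  expect_equal(irradiance_to_flux(2) / irradiance_to_flux(1), 2)
})

test_that("flux evaluation follows the half-open pulse convention", {
  stim <- light_stimulus(100, list(pulse_segment(20, 60, 5e16)),
                         background = 1e12)
  expect_identical(flux_at(stim, 10), 1e12)     # before the pulse
  expect_identical(flux_at(stim, 20), 5e16)     # onset included
  expect_identical(flux_at(stim, 59.999), 5e16)
  expect_identical(flux_at(stim, 60), 1e12)     # offset excluded
  expect_error(flux_at(stim, 101), "outside")
  expect_error(light_stimulus(100, list(pulse_segment(0, 50, 1e16),
                                        pulse_segment(40, 80, 1e16))),
               "non-overlapping")
})

test_that("per-run stimuli have the protocol's geometry", {
  rec <- make_protocol("recovery")
  stim <- stimulus_for_run(rec, 1)
  pulses <- stimulus_pulses(stim)
  expect_identical(nrow(pulses), 2L)
  expect_equal(pulses[2, 1], pulses[1, 2] + 500)  # second onset = off1 + IPI
  sp <- make_protocol("shortPulse")
  s1 <- stimulus_for_run(sp, 2)  # 1 ms duration
  expect_equal(diff(stimulus_pulses(s1)[1, ]), 1)
  expect_error(stimulus_for_run(sp, 99), "out of range")
  # segment widths plus gaps partition the total duration exactly
  for (run in c(1, 3, 5)) {
    st <- stimulus_for_run(rec, run)
    p <- stimulus_pulses(st)
    gaps <- c(p[1, 1], p[2, 1] - p[1, 2], st$duration - p[2, 2])
    expect_equal(sum(p[, 2] - p[, 1]) + sum(gaps), st$duration)
  }
})

test_that("modulated waveforms are non-negative everywhere", {
  for (name in c("sinusoid", "chirp", "ramp")) {
    spec <- make_protocol(name)
    stim <- stimulus_for_run(spec, 1)
    tt <- seq(0, stim$duration, length.out = 5000)
    expect_true(all(flux_at(stim, tt) >= 0), label = name)
  }
  # delta pulse width defaults to one output step
  d <- make_protocol("delta")
  stim <- stimulus_for_run(d, 1, dt = 0.1)
  expect_equal(diff(stimulus_pulses(stim)[1, ]), 0.1)
})
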