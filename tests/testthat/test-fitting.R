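test_that("the rectifier fit recovers E and v0 from noiseless I-V data", {
  Vs <- c(-100, -70, -40, -10, 20, 50, 80)
  E <- 0; v0 <- 43; v1 <- v1_from_constraint(E, v0)
  cc <- -0.01
  Iss <- cc * f_v(Vs, E, v0, v1) * (Vs - E)
  fit <- fit_rectifier(Vs, -Iss)   # inward-negative convention
  expect_lt(abs(fit$E - E), 1)
  expect_lt(abs(fit$v0 - v0) / v0, 0.02)
  expect_equal(fit$v1, v1_from_constraint(fit$E, fit$v0))
  # linear (non-rectifying) synthetic data drive v0 large
  Iss_lin <- 0.005 * (Vs - 5)
  fit_lin <- fit_rectifier(Vs, Iss_lin)
  expect_gt(fit_lin$v0, 1e3)
  fv_lin <- f_v(Vs, fit_lin$E, fit_lin$v0, fit_lin$v1)
  expect_lt(diff(range(fv_lin)) / mean(fv_lin), 0.05)
  # no reversal in range -> unidentifiable
  expect_error(fit_rectifier(Vs, abs(Iss) + 1), "unidentifiable")
})

test_that("the conductance estimate inverts the current equation", {
  E <- 0; v0 <- 43; v1 <- v1_from_constraint(E, v0)
  g0 <- 2.76e4; fom <- 0.73; v <- -70
  Ip <- g0 * fom * f_v(v, E, v0, v1) * (v - E) * 1e-6
  expect_equal(fit_conductance(Ip, v, E, v0, v1, f_open_max = fom), g0)
  # fallback path uses the conservative occupancy constant
  expect_equal(fit_conductance(Ip, v, E, v0, v1),
               g0 * fom / 0.8)
  expect_error(fit_conductance(Ip, E, E, v0, v1), "reversal")
})

test_that("peak-recovery fitting recovers the generating exponential", {
  t_ipi <- c(500, 1000, 2500, 5000, 10000)
  truth <- list(Ipeak0 = -1, a = 0.5, Gr0 = 3.3e-4)
  I_p <- truth$Ipeak0 - truth$a * exp(-truth$Gr0 * t_ipi)
  fit <- fit_peak_recovery(t_ipi, I_p)
  expect_equal(fit$Gr0, truth$Gr0, tolerance = 1e-6)
  expect_equal(fit$Ipeak0, truth$Ipeak0, tolerance = 1e-6)
  # short IPIs are excluded; too few points is an error
  expect_error(fit_peak_recovery(c(10, 50, 90), c(-1, -1.1, -1.2)),
               ">= 3 usable")
  # constant peaks: rate unidentifiable, flagged
  flat <- fit_peak_recovery(t_ipi, rep(-1.3, 5))
  expect_false(flat$identifiable)
  expect_true(is.na(flat$Gr0))
})

test_that("biexponential machinery reproduces known decays and the
           amplitude-weighted collapse", {
  t <- seq(0, 300, by = 0.5)
  # degenerate single-exponential decay: the amplitude-weighted rate
  # equals the generating rate and the reconstruction is exact
  fit1 <- fit_biexponential(t, -2 * exp(-0.05 * t))
  expect_equal(effective_decay_rate(list(fit1)), 0.05, tolerance = 1e-6)
  recon <- fit1$I_slow * exp(-fit1$G_slow * t) +
    fit1$I_fast * exp(-fit1$G_fast * t)
  expect_lt(max(abs(recon + 2 * exp(-0.05 * t))), 1e-8)
  # genuine biexponential
  fit2 <- fit_biexponential(t, 3 * exp(-0.1 * t) + 1 * exp(-0.02 * t))
  expect_equal(sort(c(fit2$G_slow, fit2$G_fast)), c(0.02, 0.1),
               tolerance = 1e-6)
  expect_true(fit2$G_fast >= fit2$G_slow)
  # weighted collapse to a single rate, N = 1
  eq <- effective_decay_rate(list(list(I_slow = 3, I_fast = 1,
                                       G_slow = 0.1, G_fast = 0.02)))
  expect_equal(eq, 0.08)
})

test_that("off-curve fitting collapses the 3-state decay to Gd", {
  pd <- step3_ds()
  off <- fit_off_curves(pd, chr2_params(3))
  expect_equal(off$Gd, chr2_params(3)$Gd, tolerance = 0.01)
  # every off segment is effectively single-exponential here
  for (f in off$per_trial)
    expect_lt(min(abs(c(f$I_slow, f$I_fast))) /
                max(abs(c(f$I_slow, f$I_fast))), 0.01)
})

test_that("short-pulse lag matching recovers the activation rate", {
  p6 <- chr2_params(6)
  truth <- p6; truth$Go1 <- 2; truth$Go2 <- 2
  spec <- make_protocol("shortPulse", list(durations = c(1, 2)))
  pd <- generate_protocol_data(truth, spec)
  act <- fit_activation_rates(pd, p6)
  expect_lt(abs(act$Go1 - 2) / 2, 0.1)
  expect_false(act$at_bound)
  # very fast activation: the 6-state trace approaches the 4-state one
  # and the lag collapses toward zero
  fast <- p6; fast$Go1 <- 80; fast$Go2 <- 80
  pd_fast <- generate_protocol_data(fast, spec)
  act_fast <- fit_activation_rates(pd_fast, p6)
  expect_lt(act_fast$observed_lag, act$observed_lag)
  expect_gt(act_fast$Go1, 20)
})

test_that("a single-flux data set auto-fixes the flux-dependence
           parameters", {
  p3 <- chr2_params(3)
  spec <- make_protocol("step", list(fluxes = 1e17, on_dur = 200,
                                     tail = 200))
  pd <- generate_protocol_data(p3, spec)
  init <- initial_params(3)
  init$Gd <- p3$Gd
  cfg <- fit_config(3, maxit_on = 10)
  on <- fit_on_curves(pd, init, cfg)
  expect_true(on$flux_params_fixed)
  expect_identical(on$params$phi_m, init$phi_m)
  expect_identical(on$params$p, init$p)
  expect_identical(on$params$q, init$q)
})

test_that("3-state on-curve fitting is self-consistent on noiseless
           data", {
  p3 <- chr2_params(3)
  pd <- step3_ds()
  start <- initial_params(3)
  start$Gd <- fit_off_curves(pd, p3)$Gd
  cfg <- fit_config(3, maxit_on = 60)
  on <- fit_on_curves(pd, start, cfg)
  for (nm in c("ka", "p", "phi_m"))
    expect_lt(abs(on$params[[nm]] - p3[[nm]]) / p3[[nm]], 0.05,
              label = nm)
})

test_that("refinement is a guarded descent: bypass, fixed point and
           recovery from a perturbation", {
  p3 <- chr2_params(3)
  pd <- step3_ds()
  cfg_off <- fit_config(3, refine = FALSE)
  res <- post_fit_refinement(list(pd), p3, cfg_off)
  expect_false(res$refined)
  expect_identical(res$params, p3)
  # perturb the deactivation rate: refinement must move it back and
  # reduce the residual
  pert <- p3; pert$Gd <- p3$Gd * 1.3
  cfg <- fit_config(3, maxit_refine = 30)
  ref <- post_fit_refinement(list(pd), pert, cfg)
  expect_false(ref$fell_back)
  expect_lt(ref$objective, ref$objective_stage1)
  expect_lt(abs(ref$params$Gd - p3$Gd), abs(pert$Gd - p3$Gd))
})

test_that("stage optimizations are deterministic", {
  pd <- step3_ds()
  init <- initial_params(3)
  cfg <- fit_config(3, maxit_on = 3)
  a <- fit_on_curves(pd, init, cfg)
  b <- fit_on_curves(pd, init, cfg)
  expect_identical(a$params, b$params)
  expect_identical(a$objective, b$objective)
})

test_that("fit_models requires the minimal (step) data set and skips
           absent stages", {
  expect_error(fit_models(list(), 3), "minimal set")
  pd <- step3_ds()
  cfg <- fit_config(3, maxit_on = 5, maxit_refine = 5)
  fr <- fit_models(list(step = pd), 3, config = cfg)
  expect_s3_class(fr, "fit_result")
  expect_setequal(fr$skipped, c("rectifier", "recovery"))
  init <- initial_params(3)
  expect_identical(fr$params$E, init$E)       # kept at initial
  expect_identical(fr$params$Gr0, init$Gr0)
})
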