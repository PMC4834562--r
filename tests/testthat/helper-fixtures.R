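# Shared fixtures, memoized so expensive simulations run once per session.
.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# the four-protocol noiseless verification data set (6-state truth)
verification_ds <- function() memo("verification_ds",
  verification_dataset(chr2_params(6)))

# the full staged fit on that data set (the expensive run; minutes)
verification_fit <- function() memo("verification_fit",
  fit_models(verification_ds(), 6))

# small 3-state step data set at three fluxes
step3_ds <- function() memo("step3_ds", {
  spec <- make_protocol("step",
    list(fluxes = c(1e16, 1e17, 1e18), on_dur = 300, tail = 300))
  generate_protocol_data(chr2_params(3), spec)
})

# percentage-reported parameters of the 6-state record (gamma and E are
# reported as absolute differences, not percentages)
pct_params6 <- c("g0", "phi_m", "k1", "k2", "p", "Gf0", "kf", "Gb0", "kb",
                 "q", "Go1", "Go2", "Gd1", "Gd2", "Gr0", "v0", "v1")
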