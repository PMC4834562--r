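#' Generate synthetic photocurrent data from known parameters
#'
#' Runs the forward model through a protocol and optionally adds i.i.d.
#' Gaussian noise to the current traces. With \code{noise_sd = 0} the
#' output is bit-identical to [run_protocol()]; with noise, \code{seed}
#' fully determines the data (and is mandatory — the reproducibility
#' contract of the verification procedure).
#'
#' @param params An [opsin_params()] record (the "known truth").
#' @param spec A [make_protocol()] specification.
#' @param noise_sd Gaussian noise SD on the current, nA (>= 0).
#' @param seed RNG seed, required when \code{noise_sd > 0}.
#' @param dt Output step (default [choose_dt()]).
#' @return A \code{protocol_data} set.
#' @export
generate_protocol_data <- function(params, spec, noise_sd = 0, seed = NULL,
                                   dt = choose_dt(spec)) {
  stopifnot(noise_sd >= 0)
  pd <- run_protocol(params, spec, dt = dt)
  if (noise_sd > 0) {
    if (is.null(seed))
      stop("seed is required when noise_sd > 0", call. = FALSE)
    set.seed(as.integer(seed))
    for (i in seq_along(pd$trials))
      pd$trials[[i]]$I <- pd$trials[[i]]$I +
        stats::rnorm(length(pd$trials[[i]]$I), sd = noise_sd)
  }
  pd
}

#' The synthetic verification data set
#'
#' Builds the four-protocol characterization data set used to verify the
#' fitting pipeline by parameter recovery: noiseless photocurrents
#' generated from a known 6-state parameter record under the step
#' (6 fluxes log-spaced over 2.21e15--2.65e17 photons mm^-2 s^-1),
#' rectifier (7 voltages), recovery (5 IPIs) and shortPulse (7 durations)
#' protocols.
#'
#' @param params Generating parameters (default [chr2_params()]).
#' @param noise_sd,seed Passed to [generate_protocol_data()].
#' @param protocols Character subset of the four protocol names.
#' @return Named list of \code{protocol_data} sets keyed by protocol.
#' @export
verification_dataset <- function(params = chr2_params(6), noise_sd = 0,
                                 seed = NULL,
                                 protocols = c("step", "rectifier",
                                               "recovery", "shortPulse")) {
  fluxes <- 10^seq(log10(2.21e15), log10(2.65e17), length.out = 6)
  specs <- list(
    step = make_protocol("step", list(fluxes = fluxes)),
    rectifier = make_protocol("rectifier"),
    recovery = make_protocol("recovery"),
    shortPulse = make_protocol("shortPulse"))
  out <- lapply(specs[protocols], function(sp)
    generate_protocol_data(params, sp, noise_sd = noise_sd, seed = seed))
  names(out) <- protocols
  out
}
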