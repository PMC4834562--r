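#' Convert irradiance to photon flux
#'
#' The literature quotes light intensity both as irradiance (mW mm^-2) and
#' photon flux (photons mm^-2 s^-1). Conversion requires a wavelength:
#' \eqn{\phi = P / (hc/\lambda)} with P in W mm^-2. The default 470 nm is
#' the ChR2 excitation peak.
#'
#' @param mW_per_mm2 Irradiance, mW mm^-2 (vectorized).
#' @param lambda_nm Wavelength in nm (default 470).
#' @return Photon flux, photons mm^-2 s^-1.
#' @export
#' @examples
#' irradiance_to_flux(1)  # ~2.37e15 at 470 nm
irradiance_to_flux <- function(mW_per_mm2, lambda_nm = 470) {
  h <- 6.62607015e-34; c0 <- 299792458
  e_photon <- h * c0 / (lambda_nm * 1e-9)
  mW_per_mm2 * 1e-3 / e_photon
}

#' Stimulus segment constructors
#'
#' Building blocks for [light_stimulus()] waveforms, all on half-open
#' intervals \code{[t_on, t_off)} in ms. \code{pulse_segment} is a
#' rectangular pulse of constant flux; \code{ramp_segment} interpolates
#' linearly between two flux values; \code{sinusoid_segment} and
#' \code{chirp_segment} are offset-modulated waveforms
#' \eqn{\phi_0 (1 + d \sin(\cdot))} whose modulation depth \eqn{d \le 1}
#' keeps the flux non-negative everywhere (the chirp sweeps its frequency
#' linearly from \code{f0_hz} to \code{f1_hz}).
#'
#' @param t_on,t_off Segment boundaries, ms.
#' @param phi,phi0 Flux amplitude (photons mm^-2 s^-1).
#' @param phi_start,phi_end Ramp endpoint fluxes.
#' @param freq_hz,f0_hz,f1_hz Modulation frequencies, Hz.
#' @param depth Modulation depth in [0, 1].
#' @return A segment descriptor list for [light_stimulus()].
#' @export
pulse_segment <- function(t_on, t_off, phi) {
  stopifnot(t_off > t_on, phi >= 0)
  list(type = "constant", t_on = t_on, t_off = t_off, phi = phi)
}

#' @rdname pulse_segment
#' @export
ramp_segment <- function(t_on, t_off, phi_start, phi_end) {
  stopifnot(t_off > t_on, phi_start >= 0, phi_end >= 0)
  list(type = "ramp", t_on = t_on, t_off = t_off,
       phi_start = phi_start, phi_end = phi_end)
}

#' @rdname pulse_segment
#' @export
sinusoid_segment <- function(t_on, t_off, phi0, freq_hz, depth = 1) {
  stopifnot(t_off > t_on, phi0 >= 0, freq_hz > 0, depth >= 0, depth <= 1)
  list(type = "sinusoid", t_on = t_on, t_off = t_off, phi = phi0,
       freq_hz = freq_hz, depth = depth)
}

#' @rdname pulse_segment
#' @export
chirp_segment <- function(t_on, t_off, phi0, f0_hz, f1_hz, depth = 1) {
  stopifnot(t_off > t_on, phi0 >= 0, f0_hz > 0, f1_hz > 0,
            depth >= 0, depth <= 1)
  list(type = "chirp", t_on = t_on, t_off = t_off, phi = phi0,
       f0_hz = f0_hz, f1_hz = f1_hz, depth = depth)
}

#' Piecewise light-stimulus waveform
#'
#' A stimulus is an ordered list of non-overlapping segments (constant
#' pulses, ramps, offset sinusoids or chirps) on a background flux, over a
#' total duration. Pulse edges are exact discontinuity points: the engine
#' restarts integration at every edge. Pulses are half-open intervals
#' \code{[t_on, t_off)} — the onset sample takes the pulse value, the
#' offset sample the post-pulse value.
#'
#' @param duration Total duration, ms.
#' @param segments List of segments built with the segment constructors
#'   (see [flux_at()] for evaluation semantics).
#' @param background Background flux outside all segments (default 0).
#' @return Object of class \code{light_stimulus}.
#' @export
light_stimulus <- function(duration, segments = list(), background = 0) {
  stopifnot(duration > 0, background >= 0)
  if (length(segments)) {
    ons <- vapply(segments, `[[`, numeric(1), "t_on")
    offs <- vapply(segments, `[[`, numeric(1), "t_off")
    o <- order(ons)
    segments <- segments[o]; ons <- ons[o]; offs <- offs[o]
    if (any(ons < 0) || any(offs > duration + 1e-12))
      stop("segments must lie inside [0, duration]", call. = FALSE)
    if (length(segments) > 1 && any(ons[-1] < offs[-length(offs)] - 1e-12))
      stop("segments must be non-overlapping and ordered", call. = FALSE)
  }
  structure(list(duration = duration, segments = segments,
                 background = background),
            class = "light_stimulus")
}

#' @export
print.light_stimulus <- function(x, ...) {
  cat(sprintf("light stimulus: %g ms, %d segment(s), background %g\n",
              x$duration, length(x$segments), x$background))
  for (s in x$segments)
    cat(sprintf("  [%g, %g) ms: %s\n", s$t_on, s$t_off, s$type))
  invisible(x)
}

#' On/off pulse times of a stimulus
#'
#' @param stim A \code{light_stimulus}.
#' @return n x 2 matrix of (t_on, t_off) rows, one per segment.
#' @export
stimulus_pulses <- function(stim) {
  if (!length(stim$segments)) return(matrix(numeric(0), 0, 2))
  t(vapply(stim$segments, function(s) c(s$t_on, s$t_off), numeric(2)))
}

.segment_flux <- function(seg, t) {
  switch(seg$type,
    constant = rep(seg$phi, length(t)),
    ramp = seg$phi_start +
      (seg$phi_end - seg$phi_start) * (t - seg$t_on) / (seg$t_off - seg$t_on),
    sinusoid = seg$phi *
      (1 + seg$depth * sin(2 * pi * seg$freq_hz * (t - seg$t_on) / 1000)),
    chirp = {
      tau <- (t - seg$t_on) / 1000  # s
      Tspan <- (seg$t_off - seg$t_on) / 1000
      k <- (seg$f1_hz - seg$f0_hz) / Tspan
      seg$phi * (1 + seg$depth * sin(2 * pi * (seg$f0_hz * tau + k * tau^2 / 2)))
    },
    stop("unknown segment type ", seg$type, call. = FALSE))
}

#' Evaluate the stimulus flux at given times
#'
#' Exact piecewise evaluation with the half-open convention: at a segment
#' onset the segment value applies, at its offset the post-segment value.
#'
#' @param stim A \code{light_stimulus}.
#' @param t Times in ms, each within \code{[0, duration]}.
#' @return Flux values (photons mm^-2 s^-1), same length as \code{t}.
#' @export
flux_at <- function(stim, t) {
  if (any(t < 0 | t > stim$duration))
    stop("t outside the stimulus duration", call. = FALSE)
  out <- rep(stim$background, length(t))
  for (seg in stim$segments) {
    inside <- t >= seg$t_on & t < seg$t_off
    if (any(inside)) out[inside] <- .segment_flux(seg, t[inside])
  }
  out
}

.default_step_fluxes <- function()
  irradiance_to_flux(c(0.1, 0.5, 1, 5, 10, 50, 100))

#' Preconfigured characterization and experiment protocols
#'
#' Returns a named protocol specification with field defaults matching the
#' standard opsin characterization experiments, each overridable:
#' \describe{
#'   \item{step}{Long pulse to steady state at V = -70 mV over a series of
#'     fluxes (defaults: 0.1--100 mW mm^-2 expressed as photon flux at
#'     470 nm); reveals the flux dependence.}
#'   \item{rectifier}{One fixed flux, clamp voltages
#'     \{-100, -70, -40, -10, 20, 50, 80\} mV; reveals E, v0, v1.}
#'   \item{recovery}{Two long pulses separated by inter-pulse intervals
#'     \{0.5, 1, 2.5, 5, 10\} s at V = -70 mV; reveals the dark recovery
#'     rate Gr0.}
#'   \item{shortPulse}{Brief pulses of \{0.5, 1, 2, 3, 5, 8, 10\} ms;
#'     reveals the 6-state activation rates Go1/Go2 through the peak lag.}
#'   \item{delta}{A single one-output-step pulse.}
#'   \item{ramp}{Linear flux ramp from 0 to the nominal flux.}
#'   \item{sinusoid, chirp}{Offset-modulated waveforms (always
#'     non-negative); frequency defaults are package choices.}
#' }
#'
#' @param name Protocol name (see above).
#' @param overrides Named list of field overrides (e.g.
#'   \code{list(fluxes = 1e16)}).
#' @return Object of class \code{protocol_spec}. Its \code{runs} field holds
#'   the per-run dimension (pulse durations for shortPulse, IPIs for
#'   recovery, a single run otherwise).
#' @export
make_protocol <- function(name, overrides = list()) {
  base <- switch(name,
    step = list(fluxes = .default_step_fluxes(), voltages = -70,
                delay = 25, on_dur = 500, tail = 500, runs = 1),
    rectifier = list(fluxes = 2.65e17,
                     voltages = c(-100, -70, -40, -10, 20, 50, 80),
                     delay = 25, on_dur = 500, tail = 500, runs = 1),
    recovery = list(fluxes = 2.65e17, voltages = -70,
                    ipis = c(500, 1000, 2500, 5000, 10000),
                    delay = 50, on_dur = 250, tail = 500),
    # sub-saturating flux: short-pulse responses must still be rising at
    # the pulse end for the peak-lag analysis to apply; at saturating
    # flux the transient peak moves inside the pulse
    shortPulse = list(fluxes = 1.5e15, voltages = -70,
                      durations = c(0.5, 1, 2, 3, 5, 8, 10),
                      delay = 10, tail = 200),
    delta = list(fluxes = 2.65e17, voltages = -70,
                 delay = 10, width = NA_real_, tail = 200, runs = 1),
    ramp = list(fluxes = 2.65e17, voltages = -70,
                delay = 25, on_dur = 500, tail = 500, runs = 1),
    sinusoid = list(fluxes = 2.65e17, voltages = -70, delay = 25,
                    on_dur = 1000, tail = 200, freq_hz = 5, depth = 1,
                    runs = 1),
    chirp = list(fluxes = 2.65e17, voltages = -70, delay = 25,
                 on_dur = 1000, tail = 200, f0_hz = 0.5, f1_hz = 20,
                 depth = 1, runs = 1),
    stop("unknown protocol name: ", name, call. = FALSE))
  bad <- setdiff(names(overrides), c(names(base), "runs"))
  if (length(bad))
    stop("invalid override(s) for protocol ", name, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  base[names(overrides)] <- overrides
  spec <- c(list(name = name), base)
  if (name == "recovery") {
    if (length(spec$ipis) < 2) stop("recovery needs >= 2 IPIs", call. = FALSE)
    spec$runs <- length(spec$ipis)
  }
  if (name == "shortPulse") {
    if (any(spec$durations <= 0))
      stop("shortPulse durations must be > 0", call. = FALSE)
    spec$runs <- length(spec$durations)
  }
  if (!length(spec$fluxes) || !length(spec$voltages))
    stop("protocol needs at least one flux and one voltage", call. = FALSE)
  if (any(spec$fluxes < 0)) stop("fluxes must be non-negative", call. = FALSE)
  class(spec) <- "protocol_spec"
  spec
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat(sprintf("protocol '%s': %d run(s) x %d flux(es) x %d voltage(s)\n",
              x$name, x$runs, length(x$fluxes), length(x$voltages)))
  invisible(x)
}

#' Build the light stimulus for one protocol run
#'
#' @param spec A \code{protocol_spec}.
#' @param run Run index (1-based; recovery runs map to IPIs, shortPulse
#'   runs to pulse durations).
#' @param phi Flux amplitude for the run (defaults to the first flux of
#'   the spec).
#' @param dt Output step, used only to resolve the width of a
#'   \code{delta} pulse (one output step).
#' @return A [light_stimulus()].
#' @export
stimulus_for_run <- function(spec, run, phi = spec$fluxes[1], dt = 0.1) {
  stopifnot(inherits(spec, "protocol_spec"))
  if (run < 1 || run > spec$runs)
    stop("run index out of range", call. = FALSE)
  d <- spec$delay
  switch(spec$name,
    recovery = {
      ipi <- spec$ipis[run]
      on1 <- d; off1 <- d + spec$on_dur
      on2 <- off1 + ipi; off2 <- on2 + spec$on_dur
      light_stimulus(off2 + spec$tail,
                     list(pulse_segment(on1, off1, phi),
                          pulse_segment(on2, off2, phi)))
    },
    shortPulse = {
      w <- spec$durations[run]
      light_stimulus(d + w + spec$tail, list(pulse_segment(d, d + w, phi)))
    },
    delta = {
      w <- if (is.na(spec$width)) dt else spec$width
      light_stimulus(d + w + spec$tail, list(pulse_segment(d, d + w, phi)))
    },
    ramp = light_stimulus(d + spec$on_dur + spec$tail,
                          list(ramp_segment(d, d + spec$on_dur, 0, phi))),
    sinusoid = light_stimulus(d + spec$on_dur + spec$tail,
      list(sinusoid_segment(d, d + spec$on_dur, phi / 2, spec$freq_hz,
                            spec$depth))),
    chirp = light_stimulus(d + spec$on_dur + spec$tail,
      list(chirp_segment(d, d + spec$on_dur, phi / 2, spec$f0_hz,
                         spec$f1_hz, spec$depth))),
    # step, rectifier: one long pulse
    light_stimulus(d + spec$on_dur + spec$tail,
                   list(pulse_segment(d, d + spec$on_dur, phi)))
  )
}
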