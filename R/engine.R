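#' Output time-step for a protocol
#'
#' The output sampling step follows the shortest stimulation feature:
#' \code{dt = min(shortest pulse width, shortest gap) / 10}, clamped to
#' \code{[1e-3, 0.1]} ms. Integration itself is either analytic (per
#' constant-flux segment) or adaptive, so \code{dt} only controls the
#' sampling grid.
#'
#' @param spec A [make_protocol()] specification.
#' @return dt in ms.
#' @export
choose_dt <- function(spec) {
  stopifnot(inherits(spec, "protocol_spec"))
  widths <- c(spec$on_dur, spec$durations, spec$width)
  gaps <- c(spec$delay, spec$tail, spec$ipis)
  cand <- c(widths, gaps)
  cand <- cand[is.finite(cand) & cand > 0]
  if (!length(cand)) return(0.1)
  min(max(min(cand) / 10, 1e-3), 0.1)
}

# eigenmode propagation of the LTI system dx/dt = A x: states at offsets
# taus from x0. Returns n x length(taus). NULL if the eigenbasis is
# ill-conditioned (caller falls back to lsoda).
.propagate_const <- function(A, x0, taus) {
  eg <- eigen(A)
  V <- eg$vectors
  k <- tryCatch(kappa(V), error = function(e) Inf)
  if (!is.finite(k) || k > 1e12) return(NULL)
  coef <- tryCatch(solve(V, x0), error = function(e) NULL)
  if (is.null(coef)) return(NULL)
  X <- V %*% (coef * exp(outer(eg$values, taus)))
  Re(X)
}

.lsoda_states <- function(params, stim, t0, t1, x0, out_times,
                          rtol, atol, constant_phi = NULL) {
  rhs <- if (is.null(constant_phi)) {
    function(t, y, parms) {
      A <- rate_matrix(transition_rates(params, flux_at(stim, min(t, stim$duration))))
      list(drop(A %*% y))
    }
  } else {
    A <- rate_matrix(transition_rates(params, constant_phi))
    function(t, y, parms) list(drop(A %*% y))
  }
  tt <- unique(sort(c(t0, out_times, t1)))
  sol <- deSolve::ode(y = x0, times = tt, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop(sprintf("ODE solver failed on segment [%g, %g] ms", t0, t1),
         call. = FALSE)
  sol
}

#' Simulate state occupancies over a stimulus
#'
#' Integrates the photocycle ODEs piecewise between stimulus
#' discontinuities, restarting at every pulse edge so discontinuities never
#' fall inside a solver step. Within constant-flux segments the system is
#' linear time-invariant and is propagated by its exact eigenmode solution
#' (method \code{"auto"}, the default); time-varying segments (ramp,
#' sinusoid, chirp) and \code{method = "lsoda"} use the adaptive stiff
#' solver with \code{rtol = 1e-8}, \code{atol = 1e-10}.
#'
#' @param params An [opsin_params()] record.
#' @param stim A [light_stimulus()].
#' @param times Output times (ms), strictly increasing, within the
#'   stimulus duration, starting at 0.
#' @param state0 Initial occupancy (defaults to the dark ground state).
#' @param method \code{"auto"} or \code{"lsoda"}.
#' @param rtol,atol Solver tolerances for the lsoda path.
#' @return Matrix \code{length(times) x n_states} of occupancies, columns
#'   named by [state_names()].
#' @export
simulate_states <- function(params, stim, times,
                            state0 = ground_state(params$model_order),
                            method = c("auto", "lsoda"),
                            rtol = 1e-8, atol = 1e-10) {
  method <- match.arg(method)
  n <- params$model_order
  stopifnot(length(state0) == length(state_names(n)))
  if (abs(sum(state0) - 1) > 1e-9)
    stop("state0 must sum to 1", call. = FALSE)
  pulses <- stimulus_pulses(stim)
  edges <- sort(unique(c(0, pulses, stim$duration)))
  edges <- edges[edges <= stim$duration + 1e-12]
  out <- matrix(NA_real_, length(times), length(state0),
                dimnames = list(NULL, state_names(n)))
  x <- as.numeric(state0)
  seg_types <- vapply(stim$segments, `[[`, character(1), "type")
  for (i in seq_len(length(edges) - 1)) {
    e0 <- edges[i]; e1 <- edges[i + 1]
    last <- i == length(edges) - 1
    sel <- times >= e0 - 1e-12 & (if (last) times <= e1 + 1e-12
                                  else times < e1 - 1e-12)
    tsel <- times[sel]
    # which segment governs this interval?
    seg_idx <- which(vapply(stim$segments, function(s)
      s$t_on <= e0 + 1e-12 && s$t_off >= e1 - 1e-12, logical(1)))
    varying <- length(seg_idx) && seg_types[seg_idx[1]] != "constant"
    if (!varying && method == "auto") {
      phi0 <- flux_at(stim, e0)
      A <- rate_matrix(transition_rates(params, phi0))
      X <- .propagate_const(A, x, c(tsel - e0, e1 - e0))
      if (!is.null(X)) {
        if (length(tsel)) out[sel, ] <- t(X[, seq_along(tsel), drop = FALSE])
        x <- X[, ncol(X)]
        next
      }
    }
    phi_const <- if (!varying) flux_at(stim, e0) else NULL
    sol <- .lsoda_states(params, stim, e0, e1, x, tsel, rtol, atol,
                         constant_phi = phi_const)
    if (length(tsel))
      out[sel, ] <- sol[match(tsel, sol[, 1]), -1, drop = FALSE]
    x <- as.numeric(sol[nrow(sol), -1])
  }
  out
}

#' Simulate a voltage-clamped photocurrent
#'
#' Runs [simulate_states()] and converts occupancies to current via the
#' conductance factorization. The result is a [photocurrent()] carrying
#' the full state trajectory.
#'
#' @inheritParams simulate_states
#' @param v Clamp voltage, mV.
#' @param dt Output step, ms (ignored when \code{times} is given).
#' @param times Optional explicit output grid starting at 0.
#' @return A [photocurrent()] with the state trajectory in \code{$states}.
#' @export
simulate_photocurrent <- function(params, stim, v = -70,
                                  state0 = ground_state(params$model_order),
                                  dt = 0.1, times = NULL,
                                  method = c("auto", "lsoda"),
                                  rtol = 1e-8, atol = 1e-10) {
  method <- match.arg(method)
  if (is.null(times)) {
    nstep <- floor(stim$duration / dt + 1e-9)
    times <- (0:nstep) * dt
    if (times[length(times)] < stim$duration - 1e-9)
      times <- c(times, stim$duration)
  }
  states <- simulate_states(params, stim, times, state0, method, rtol, atol)
  I <- photocurrent_of_state(params, states, v)
  phis <- vapply(stim$segments, function(s)
    max(.segment_flux(s, c(s$t_on, (s$t_on + s$t_off) / 2))), numeric(1))
  phi_nominal <- if (length(phis)) max(phis) else stim$background
  photocurrent(I = I, t = times, pulses = stimulus_pulses(stim),
               phi = phi_nominal, V = v, states = states)
}

#' Run a model through a full protocol
#'
#' Simulates one photocurrent per (run, flux, voltage) combination of the
#' protocol, all starting from the dark ground state, and collects them in
#' a [protocol_data()] set.
#'
#' @param params An [opsin_params()] record.
#' @param spec A [make_protocol()] specification.
#' @param dt Output step (default from [choose_dt()]).
#' @return A \code{protocol_data} object.
#' @export
run_protocol <- function(params, spec, dt = choose_dt(spec)) {
  stopifnot(inherits(spec, "protocol_spec"))
  pd <- protocol_data(spec$name, n_runs = spec$runs, phis = spec$fluxes,
                      Vs = spec$voltages)
  for (run in seq_len(spec$runs))
    for (phi in spec$fluxes)
      for (v in spec$voltages) {
        stim <- stimulus_for_run(spec, run, phi = phi, dt = dt)
        pc <- simulate_photocurrent(params, stim, v = v, dt = dt)
        pc$phi <- phi   # annotate with the protocol's grid flux
        pd <- add_trial(pd, pc, run = run)
      }
  pd
}
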