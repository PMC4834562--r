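#' Hill-saturating light-dependent rate
#'
#' All light-dependent transition rates of the photocycle models share the
#' saturating form
#' \deqn{G(\phi) = k\,\frac{\phi^e}{\phi^e + \phi_m^e} + G_{dark},}
#' where \eqn{\phi} is the photon flux, \eqn{\phi_m} the half-saturation
#' flux and \eqn{e} a Hill exponent.
#'
#' @param phi Photon flux, photons mm^-2 s^-1 (non-negative; vectorized).
#' @param k Maximal light-driven rate coefficient, ms^-1 (> 0).
#' @param phi_m Half-saturation flux (> 0).
#' @param exponent Hill exponent (> 0).
#' @param baseline Dark (light-independent) rate added to the Hill term,
#'   ms^-1 (>= 0). Default 0.
#' @return Rate in ms^-1; monotone non-decreasing in \code{phi} and bounded
#'   by \code{k + baseline}.
#' @export
#' @examples
#' hill_rate(5.07e17, k = 18.5, phi_m = 5.07e17, exponent = 0.982) # = k/2
hill_rate <- function(phi, k, phi_m, exponent, baseline = 0) {
  if (any(phi < 0)) stop("flux phi must be non-negative", call. = FALSE)
  stopifnot(k > 0, phi_m > 0, exponent > 0, baseline >= 0)
  # ratio form avoids overflow of phi^e for large fluxes
  r <- (phi / phi_m)^exponent
  k * r / (r + 1) + baseline
}

#' Instantaneous transition rates at a given flux
#'
#' Evaluates every light-dependent transition of the model via
#' [hill_rate()] and copies the light-independent rates from the parameter
#' record. In darkness (\eqn{\phi = 0}) the activation rates vanish and the
#' O1/O2 interconversion rates reduce to their dark values \code{Gf0},
#' \code{Gb0} (3-state: recovery reduces to \code{Gr0}).
#'
#' @param params An [opsin_params()] record.
#' @param phi Photon flux (scalar, >= 0).
#' @return A named list of rates, ms^-1, with a \code{model_order} entry:
#'   3-state \code{Ga, Gd, Gr}; 4-state \code{Ga1, Ga2, Gf, Gb, Gd1, Gd2,
#'   Gr0}; 6-state additionally \code{Go1, Go2}.
#' @export
transition_rates <- function(params, phi) {
  stopifnot(inherits(params, "opsin_params"), length(phi) == 1L)
  if (phi < 0) stop("flux phi must be non-negative", call. = FALSE)
  n <- params$model_order
  if (n == 3L) {
    list(model_order = 3L,
         Ga = hill_rate(phi, params$ka, params$phi_m, params$p),
         Gd = params$Gd,
         Gr = hill_rate(phi, params$kr, params$phi_m, params$q, params$Gr0))
  } else {
    r <- list(model_order = n,
              Ga1 = hill_rate(phi, params$k1, params$phi_m, params$p),
              Ga2 = hill_rate(phi, params$k2, params$phi_m, params$p),
              Gf  = hill_rate(phi, params$kf, params$phi_m, params$q, params$Gf0),
              Gb  = hill_rate(phi, params$kb, params$phi_m, params$q, params$Gb0),
              Gd1 = params$Gd1, Gd2 = params$Gd2, Gr0 = params$Gr0)
    if (n == 6L) { r$Go1 <- params$Go1; r$Go2 <- params$Go2 }
    r
  }
}

#' Transition-rate matrix of the photocycle
#'
#' Builds the generator matrix A of the linear system
#' \eqn{\dot{x} = A x} over the state occupancies, in the fixed state
#' ordering of [state_names()]. Columns of A sum to zero (conservation of
#' total occupancy).
#'
#' @param rates Output of [transition_rates()].
#' @return Square numeric matrix with dimnames set to the state names.
#' @export
rate_matrix <- function(rates) {
  n <- rates$model_order
  if (n == 3L) {
    with(rates, matrix(c(
      -Ga,  0,  Gr,
       Ga, -Gd,  0,
        0,  Gd, -Gr), 3, 3, byrow = TRUE,
      dimnames = list(state_names(3), state_names(3))))
  } else if (n == 4L) {
    with(rates, matrix(c(
      -Ga1,        Gd1,         0,          Gr0,
       Ga1, -(Gd1 + Gf),        Gb,           0,
         0,         Gf, -(Gd2 + Gb),        Ga2,
         0,          0,        Gd2, -(Gr0 + Ga2)), 4, 4, byrow = TRUE,
      dimnames = list(state_names(4), state_names(4))))
  } else {
    with(rates, matrix(c(
      -Ga1,    0,        Gd1,         0,    0,          Gr0,
       Ga1, -Go1,          0,         0,    0,            0,
         0,  Go1, -(Gd1+Gf),         Gb,    0,            0,
         0,    0,         Gf, -(Gd2+Gb),  Go2,            0,
         0,    0,          0,         0, -Go2,          Ga2,
         0,    0,          0,       Gd2,    0, -(Gr0 + Ga2)), 6, 6,
      byrow = TRUE, dimnames = list(state_names(6), state_names(6))))
  }
}

#' Time derivatives of the state occupancies
#'
#' @param state Numeric occupancy vector in the model's state order.
#' @param rates Output of [transition_rates()].
#' @return Per-state derivatives, ms^-1; they sum to zero.
#' @export
ode_rhs <- function(state, rates) {
  A <- rate_matrix(rates)
  if (length(state) != nrow(A))
    stop("state has length ", length(state), " but the ", rates$model_order,
         "-state model expects ", nrow(A), call. = FALSE)
  drop(A %*% state)
}

#' Ground (fully dark-adapted) state
#'
#' @param model_order 3, 4 or 6.
#' @return Occupancy vector with all probability in C (3-state) or C1.
#' @export
ground_state <- function(model_order) {
  s <- setNames(numeric(length(state_names(model_order))),
                state_names(model_order))
  s[1] <- 1
  s
}

#' Steady-state occupancy under constant illumination
#'
#' Solves for the unique normalized null-space direction of the rate
#' matrix. For the 3-state model this equals
#' \eqn{O_{ss} = G_a G_r / (G_a G_d + G_a G_r + G_d G_r)} with C and D given
#' by the cycle's balance.
#'
#' @param params An [opsin_params()] record.
#' @param phi Constant photon flux (>= 0).
#' @return Named occupancy vector summing to 1.
#' @export
steady_state <- function(params, phi) {
  rates <- transition_rates(params, phi)
  A <- rate_matrix(rates)
  n <- nrow(A)
  # replace the conservation-redundant last row with the normalization
  M <- A
  M[n, ] <- 1
  b <- c(rep(0, n - 1), 1)
  x <- tryCatch(solve(M, b), error = function(e) NULL)
  if (is.null(x) || any(!is.finite(x)) || any(x < -1e-9))
    stop("steady state is not unique (reducible rate matrix at phi = ",
         phi, ")", call. = FALSE)
  x <- pmax(x, 0)
  setNames(x / sum(x), rownames(A))
}

#' Closed-form 3-state trajectory under constant flux
#'
#' Using conservation (C + O + D = 1) the 3-state photocycle reduces to a
#' 2-variable affine linear system in (C, O); its solution is the fixed
#' point plus two exponential modes with rates given by the eigenvalues of
#' the reduced 2x2 matrix. Repeated eigenvalues (a measure-zero degeneracy)
#' fall back to numerical integration, flagged via the \code{"degenerate"}
#' attribute.
#'
#' @param params A 3-state [opsin_params()] record.
#' @param phi Constant photon flux (>= 0).
#' @param state0 Initial occupancy (C, O, D); default ground state.
#' @param times Ordered output times, ms (first may be > 0; the initial
#'   condition applies at t = times[1]).
#' @return Matrix with columns \code{t, C, O, D}.
#' @export
analytic_three_state <- function(params, phi, state0 = ground_state(3),
                                 times) {
  stopifnot(inherits(params, "opsin_params"), params$model_order == 3L)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing",
                                  call. = FALSE)
  if (abs(sum(state0) - 1) > 1e-9)
    stop("state0 must sum to 1", call. = FALSE)
  r <- transition_rates(params, phi)
  # reduced system: d/dt (C,O) = M (C,O) + b with D = 1 - C - O
  M <- matrix(c(-(r$Ga + r$Gr), -r$Gr,
                r$Ga,           -r$Gd), 2, 2, byrow = TRUE)
  b <- c(r$Gr, 0)
  eg <- eigen(M)
  if (abs(eg$values[1] - eg$values[2]) <
      1e-9 * max(abs(eg$values), 1e-12)) {
    # defective/degenerate pair: integrate numerically instead
    stim <- light_stimulus(duration = max(times) + 1,
                           segments = list(pulse_segment(0, max(times) + 1, phi)))
    pc <- simulate_photocurrent(params, stim, v = -70, state0 = state0,
                                method = "lsoda",
                                times = times - times[1])
    out <- cbind(t = times, pc$states)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  xstar <- solve(M, -b)
  tau <- times - times[1]
  coef <- solve(eg$vectors, state0[1:2] - xstar)
  modes <- exp(outer(eg$values, tau))            # 2 x T
  X <- eg$vectors %*% (coef * modes)             # 2 x T
  X <- Re(X) + matrix(Re(xstar), 2, length(tau))
  out <- cbind(t = times, C = X[1, ], O = X[2, ], D = 1 - X[1, ] - X[2, ])
  attr(out, "degenerate") <- FALSE
  out
}

#' Photocycle conductance factor
#'
#' The open-state contribution to the conductance: \eqn{f_\phi = O} for the
#' 3-state model and \eqn{f_\phi = O_1 + \gamma O_2} for the 4- and 6-state
#' models, where \eqn{\gamma = g_{O2}/g_{O1}} is the open-state conductance
#' ratio. \code{gamma = 0} exactly is allowed.
#'
#' @param state Occupancy vector (model order inferred from its length), or
#'   a trajectory matrix with named state columns.
#' @param gamma Open-state conductance ratio (ignored for 3-state).
#' @return Dimensionless factor in \eqn{[0, 1 + \gamma]}.
#' @export
f_phi <- function(state, gamma = 0) {
  if (is.matrix(state)) {
    if ("O" %in% colnames(state)) return(state[, "O"])
    return(state[, "O1"] + gamma * state[, "O2"])
  }
  n <- length(state)
  if (n == 3L) state[[2]]
  else if (n == 4L) state[[2]] + gamma * state[[3]]
  else if (n == 6L) state[[3]] + gamma * state[[4]]
  else stop("state must have length 3, 4 or 6", call. = FALSE)
}

#' Voltage rectification factor
#'
#' Empirical inward-rectification factor
#' \deqn{f_v(v) = \frac{v_1}{v - E}\left(1 - e^{-(v-E)/v_0}\right),}
#' normalized so that \eqn{f_v(-70) = 1} when \code{v1} satisfies the
#' constraint of [v1_from_constraint()]. The removable singularity at
#' \eqn{v = E} is evaluated by a second-order series for
#' \eqn{|v - E| < 10^{-3} |v_0|}, which avoids catastrophic cancellation;
#' the analytic limit at \eqn{v = E} is \eqn{v_1/v_0}. For large \code{v0}
#' the factor tends to the constant \eqn{v_1/v_0} (linear, non-rectifying
#' regime).
#'
#' @param v Membrane voltage, mV (vectorized).
#' @param E Reversal potential, mV.
#' @param v0,v1 Rectification shape and amplitude parameters, mV
#'   (\code{v0} non-zero).
#' @return Dimensionless factor.
#' @export
f_v <- function(v, E, v0, v1) {
  if (v0 == 0) stop("v0 must be non-zero", call. = FALSE)
  u <- v - E
  small <- abs(u) < 1e-3 * abs(v0)
  out <- numeric(length(u))
  if (any(!small)) {
    ub <- u[!small]
    out[!small] <- v1 * (1 - exp(-ub / v0)) / ub
  }
  if (any(small)) {
    us <- u[small]
    # (1 - e^{-x})/x = 1 - x/2 + x^2/6 + O(x^3), x = u/v0
    x <- us / v0
    out[small] <- (v1 / v0) * (1 - x / 2 + x^2 / 6)
  }
  out
}

#' Photocurrent from conductance factorization
#'
#' \deqn{I = g_0 \, f_\phi \, f_v(v) \, (v - E) \times 10^{-6},}
#' the factor \eqn{10^{-6}} converting pS x mV to nA. Inward (negative)
#' current results for \eqn{v < E} whenever the photocycle factor is
#' positive.
#'
#' @param params An [opsin_params()] record.
#' @param state Occupancy vector or trajectory matrix.
#' @param v Membrane voltage, mV.
#' @return Current in nA (vector if \code{state} is a trajectory).
#' @export
photocurrent_of_state <- function(params, state, v) {
  gam <- if (is.null(params$gamma)) 0 else params$gamma
  fphi <- f_phi(state, gam)
  fv <- f_v(v, params$E, params$v0, params$v1)
  params$g0 * fphi * fv * (v - params$E) * 1e-6
}
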