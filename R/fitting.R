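#' Configuration for the staged fitting pipeline
#'
#' @param model_order 3, 4 or 6.
#' @param optimizer Optimizer for the on-curve and refinement stages;
#'   \code{"powell"} (the default and currently only choice) uses
#'   [powell_minimize()].
#' @param refine Run the joint post-fit refinement stage (default TRUE).
#' @param refine_bounds Lower/upper bound fractions applied to the
#'   dark/activation parameters during refinement (default 0.5 and 2.0,
#'   i.e. 50--200\% of their stage-1 values).
#' @param min_ipi Minimum inter-pulse interval (ms) admitted to the
#'   peak-recovery fit; shorter IPIs are distorted by the fast transitions
#'   (default 100 ms).
#' @param fallback_open_frac Open-state occupancy assumed by the
#'   conductance estimate before any kinetic stage has run (around 0.8 for
#'   wild-type ChR2).
#' @param fixed Names of parameters to hold at their initial values
#'   throughout.
#' @param bounds Named list of \code{c(lower, upper)} overrides of the
#'   default fitting bounds.
#' @param maxit_on,maxit_refine Powell sweep limits for the two
#'   optimization stages.
#' @param plateau Plateau-detector settings, see [plateau_config()].
#' @return List of class \code{fit_config}.
#' @export
fit_config <- function(model_order = 6, optimizer = "powell", refine = TRUE,
                       refine_bounds = c(0.5, 2), min_ipi = 100,
                       fallback_open_frac = 0.8, fixed = character(),
                       bounds = list(), maxit_on = 60, maxit_refine = 160,
                       plateau = plateau_config()) {
  optimizer <- match.arg(optimizer, "powell")
  stopifnot(refine_bounds[1] > 0, refine_bounds[1] < 1, refine_bounds[2] > 1)
  structure(list(model_order = as.integer(model_order),
                 optimizer = optimizer, refine = refine,
                 refine_bounds = refine_bounds, min_ipi = min_ipi,
                 fallback_open_frac = fallback_open_frac, fixed = fixed,
                 bounds = bounds, maxit_on = maxit_on,
                 maxit_refine = maxit_refine, plateau = plateau),
            class = "fit_config")
}

# default fitting bounds (natural units) and scale per parameter
.default_bounds <- list(
  phi_m = c(1e15, 1e20), k1 = c(0.05, 500), k2 = c(0.05, 500),
  ka = c(0.05, 500), kr = c(1e-4, 10), p = c(0.2, 4), q = c(0.2, 4),
  kf = c(1e-3, 10), kb = c(1e-3, 10), Gf0 = c(1e-4, 1), Gb0 = c(1e-4, 1),
  Gd = c(1e-3, 2), Gd1 = c(1e-3, 2), Gd2 = c(1e-4, 1),
  Go1 = c(0.05, 100), Go2 = c(0.05, 100), gamma = c(0, 1),
  Gr0 = c(1e-6, 0.1))

.param_scale_type <- function(name) if (name == "gamma") "linear" else "log"

.to_box <- function(v, name, b) {
  if (.param_scale_type(name) == "linear") (v - b[1]) / (b[2] - b[1])
  else (log(v) - log(b[1])) / (log(b[2]) - log(b[1]))
}

.from_box <- function(z, name, b) {
  if (.param_scale_type(name) == "linear") b[1] + z * (b[2] - b[1])
  else exp(log(b[1]) + z * (log(b[2]) - log(b[1])))
}

# piecewise-constant-flux state simulation on a fixed grid (fitting
# workhorse; no stimulus objects, minimal overhead). With `rows` given,
# only those state rows are returned (the conductance needs just the open
# states); the segment handoff always uses the full state.
.sim_states_fast <- function(params, edges, fluxes, times, rows = NULL,
                             cache = NULL) {
  nm <- state_names(params$model_order)
  keep <- if (is.null(rows)) seq_along(nm) else rows
  out <- matrix(NA_real_, length(times), length(keep),
                dimnames = list(NULL, nm[keep]))
  g <- ground_state(params$model_order)
  x <- g
  m <- length(fluxes)
  done <- 0L
  for (i in seq_len(m)) {
    e0 <- edges[i]; e1 <- edges[i + 1]
    sel <- if (i == m) times >= e0 - 1e-12
           else times >= e0 - 1e-12 & times < e1 - 1e-12
    tsel <- times[sel]
    # the dark ground state is a fixed point: nothing to integrate
    if (fluxes[i] == 0 && max(abs(x - g)) < 1e-14) {
      if (length(tsel)) {
        out[sel, ] <- matrix(g[keep], length(tsel), length(keep),
                             byrow = TRUE)
        done <- done + length(tsel)
      }
      next
    }
    key <- as.character(fluxes[i])
    eg <- if (!is.null(cache) && !is.null(cache[[key]])) cache[[key]]
    else {
      A <- rate_matrix(transition_rates(params, fluxes[i]))
      e <- eigen(A, symmetric = FALSE)
      e$A <- A
      if (!is.null(cache)) cache[[key]] <- e
      e
    }
    V <- eg$vectors
    coef <- tryCatch(solve(V, x), error = function(e) NULL)
    ok <- !is.null(coef) &&
      max(abs(Re(V %*% coef) - x)) < 1e-9
    if (ok) {
      if (length(tsel)) {
        modes <- exp(outer(eg$values, tsel - e0))
        out[sel, ] <- t(Re(V[keep, , drop = FALSE] %*% (coef * modes)))
        done <- done + length(tsel)
      }
      if (done >= length(times) && i < m) break
      x <- Re(drop(V %*% (coef * exp(eg$values * (e1 - e0)))))
    } else {  # defective eigenbasis: adaptive solver fallback
      A <- eg$A
      tt <- unique(sort(c(0, tsel - e0, e1 - e0)))
      sol <- deSolve::ode(y = as.numeric(x), times = tt,
                          func = function(t, y, p) list(drop(A %*% y)),
                          parms = NULL, method = "lsoda",
                          rtol = 1e-10, atol = 1e-12)
      if (length(tsel)) {
        out[sel, ] <- sol[match(tsel - e0, sol[, 1]), 1 + keep,
                          drop = FALSE]
        done <- done + length(tsel)
      }
      x <- as.numeric(sol[nrow(sol), -1])
    }
  }
  out
}

.open_rows <- function(order)
  switch(as.character(order), "3" = 2L, "4" = c(2L, 3L), "6" = c(3L, 4L))

.fphi_cols <- function(S_open, order, gamma) {
  if (order == 3L) S_open[, 1] else S_open[, 1] + gamma * S_open[, 2]
}

# schedule (edges + per-interval flux) of a rectangular-pulse trial
.trial_schedule <- function(pc) {
  tmax <- pc$t[length(pc$t)]
  edges <- sort(unique(c(0, as.numeric(t(pc$pulses)), tmax)))
  edges <- edges[edges <= tmax + 1e-12]
  mids <- (edges[-length(edges)] + edges[-1]) / 2
  fluxes <- vapply(mids, function(tm) {
    inside <- any(tm >= pc$pulses[, 1] & tm < pc$pulses[, 2])
    if (inside) pc$phi else 0
  }, numeric(1))
  list(edges = edges, fluxes = fluxes)
}

# residual grid: thin long traces to ~max_pts backbone samples per trial
# (the global minimum of a noiseless exact-model fit does not depend on
# the sampling density) but keep full resolution for a short window after
# every pulse edge — the fast transients there are what identify the
# activation kinetics, and a sparse grid would let spurious solutions
# slip between samples. The observed peak sample is always kept.
.prep_trials <- function(pd, idx_mode = c("on", "all"),
                         plateau = plateau_config(), max_pts = 400L,
                         edge_window = 5) {
  idx_mode <- match.arg(idx_mode)
  lapply(seq_along(pd$trials), function(i) {
    pc <- pd$trials[[i]]
    sched <- .trial_schedule(pc)
    phases <- segment_phases(pc)
    idx <- if (idx_mode == "on") phases[[1]]$on
           else which(pc$t >= pc$pulses[1, 1] - 1e-9)
    ss <- find_steady_state(pc, config = plateau)
    pk <- find_peak(pc)
    w_ref <- if (is.finite(ss$value) && ss$at_plateau) abs(ss$value)
             else abs(pk$value)
    stride <- max(1L, length(idx) %/% max_pts)
    t_idx <- pc$t[idx]
    edges <- as.numeric(t(pc$pulses))
    dense <- idx[Reduce(`|`, lapply(edges, function(e)
      t_idx >= e - 1e-9 & t_idx < e + edge_window))]
    fit_idx <- sort(unique(c(idx[seq(1L, length(idx), by = stride)],
                             dense, intersect(pk$index, idx))))
    list(fit_times = pc$t[fit_idx], fit_I = pc$I[fit_idx],
         edges = sched$edges, fluxes = sched$fluxes,
         phi = pc$phi, V = pc$V,
         Ip = pk$value, Iss = ss$value, w = 1 / max(w_ref, 1e-12))
  })
}

# Hill-rate reparameterization: the maximal coefficients k are nearly
# degenerate with phi_m (only their combination k * Hill(phi) is seen at
# sub-saturating fluxes), so the optimizer works with the rate attained at
# a reference flux (geometric mean of the data fluxes) instead of k
# itself. This aligns the sloppy direction with the phi_m coordinate and
# conditions the search; k is recovered exactly afterwards.
.hill_coeff_names <- c("k1", "k2", "kf", "kb", "ka", "kr")

.hill_frac <- function(phi, phi_m, e) {
  r <- (phi / phi_m)^e
  r / (r + 1)
}

.k_exponent <- function(name)
  if (name %in% c("k1", "k2", "ka")) "p" else "q"

# params from a box vector: natural-scale fields first (phi_m, p, q, ...),
# then the Hill coefficients from their reference-rate coordinates
.unpack_box <- function(base_params, free, bounds, z, phi_ref) {
  p <- base_params
  kset <- free %in% .hill_coeff_names
  for (j in which(!kset))
    p[[free[j]]] <- .from_box(z[j], free[j], bounds[[free[j]]])
  for (j in which(kset)) {
    nm <- free[j]
    alpha <- .from_box(z[j], nm, bounds[[nm]])
    p[[nm]] <- alpha / .hill_frac(phi_ref, p$phi_m, p[[.k_exponent(nm)]])
  }
  p
}

.pack_box <- function(params, free, bounds, phi_ref) {
  vapply(seq_along(free), function(j) {
    nm <- free[j]
    v <- if (nm %in% .hill_coeff_names)
      params[[nm]] * .hill_frac(phi_ref, params$phi_m,
                                params[[.k_exponent(nm)]])
    else params[[nm]]
    min(max(.to_box(v, nm, bounds[[nm]]), 1e-6), 1 - 1e-6)
  }, numeric(1))
}

# box bounds: Hill coefficients get reference-rate bounds
.coord_bounds <- function(config, free, params = NULL, tight = NULL,
                          frac = c(0.5, 2)) {
  b <- .merge_bounds(config, free, params = params, tight = tight,
                     frac = frac)
  for (nm in intersect(free, .hill_coeff_names)) b[[nm]] <- c(1e-6, 1e3)
  b
}

# sum-of-squares objective over a trial set; g0 is re-derived at every
# evaluation by matching the observed peak of the maximum-flux trial
# (the conductance correction of the pipeline, internalized)
.make_objective <- function(trials, base_params, free, bounds, phi_ref) {
  imax <- which.max(vapply(trials, `[[`, numeric(1), "phi"))
  order <- base_params$model_order
  rows <- .open_rows(order)
  function(z) {
    p <- .unpack_box(base_params, free, bounds, z, phi_ref)
    gam <- if (is.null(p$gamma)) 0 else p$gamma
    cache <- new.env(parent = emptyenv())
    # max-flux trial first: fixes g0 by peak matching
    tmax <- trials[[imax]]
    Fmax <- .fphi_cols(.sim_states_fast(p, tmax$edges, tmax$fluxes,
                                        tmax$fit_times, rows = rows,
                                        cache = cache),
                       order, gam)
    fom <- max(Fmax)
    fv_max <- f_v(tmax$V, p$E, p$v0, p$v1)
    denom <- fom * fv_max * (tmax$V - p$E) * 1e-6
    if (!is.finite(denom) || abs(denom) < 1e-300) return(1e12)
    p$g0 <- tmax$Ip / denom
    if (!is.finite(p$g0) || p$g0 <= 0) return(1e12)
    total <- 0
    for (k in seq_along(trials)) {
      tr <- trials[[k]]
      fphi <- if (k == imax) Fmax
              else .fphi_cols(.sim_states_fast(p, tr$edges, tr$fluxes,
                                               tr$fit_times, rows = rows,
                                               cache = cache),
                              order, gam)
      I_model <- p$g0 * fphi * f_v(tr$V, p$E, p$v0, p$v1) *
        (tr$V - p$E) * 1e-6
      r <- (I_model - tr$fit_I) * tr$w
      total <- total + sum(r * r)
    }
    if (!is.finite(total)) 1e12 else total
  }
}

# conductance correction: g0 from the observed max-flux peak and the
# simulated maximal photocycle factor under the given kinetics
.g0_peak_match <- function(params, trials) {
  imax <- which.max(vapply(trials, `[[`, numeric(1), "phi"))
  tmax <- trials[[imax]]
  order <- params$model_order
  gam <- if (is.null(params$gamma)) 0 else params$gamma
  S <- .sim_states_fast(params, tmax$edges, tmax$fluxes, tmax$fit_times,
                        rows = .open_rows(order))
  fit_conductance(tmax$Ip, tmax$V, params$E, params$v0, params$v1,
                  f_open_max = max(.fphi_cols(S, order, gam)))
}

# Powell with fresh-direction restarts: the direction set is re-seeded
# with the identity whenever a cycle converges, until restarts stop
# paying (standard practice for curved valleys)
.run_box_optim <- function(obj, z0, maxit, restarts = 8L,
                           sweeps_per_start = 40L) {
  z <- z0
  total_ev <- 0L; total_it <- 0L
  val <- Inf
  for (r in seq_len(restarts)) {
    res <- powell_minimize(obj, z, lower = 0, upper = 1,
                           maxit = min(sweeps_per_start, maxit - total_it),
                           reltol = 1e-13, ls_tol = 1e-8)
    total_ev <- total_ev + res$counts
    total_it <- total_it + res$iterations
    moved <- max(abs(res$par - z))
    improved <- val - res$value
    z <- res$par; val <- res$value
    if (total_it >= maxit) break
    if (r > 1 && (moved < 1e-9 || improved < 1e-12 * max(val, 1e-12)))
      break
  }
  list(par = z, value = val, counts = total_ev, iterations = total_it,
       converged = TRUE, restarts = r)
}

.merge_bounds <- function(config, free, params = NULL, tight = NULL,
                          frac = c(0.5, 2)) {
  b <- .default_bounds
  for (nm in names(config$bounds)) b[[nm]] <- config$bounds[[nm]]
  if (!is.null(tight))
    for (nm in tight)
      b[[nm]] <- sort(params[[nm]] * frac)
  b[free]
}

#' Fit the voltage rectification parameters
#'
#' Estimates the reversal potential E from the zero crossing of the
#' steady-state current-voltage relation (linear interpolation between the
#' bracketing voltages as the starting value), then least-squares fits
#' \eqn{I_{ss}(V) = c \, f_v(V) \, (V - E)} with \code{v1} tied to the
#' normalization constraint. Voltages within 10 mV of the crossing are
#' down-weighted since they distort the fit.
#'
#' @param Vs Clamp voltages, mV (>= 5 values spanning the reversal).
#' @param Iss Steady-state currents, nA, matching \code{Vs}.
#' @param v0_init Starting value for \code{v0} (default 43 mV).
#' @return List with \code{E}, \code{v0}, \code{v1}, the scale \code{c}
#'   and the residual norm.
#' @export
fit_rectifier <- function(Vs, Iss, v0_init = 43) {
  o <- order(Vs); Vs <- Vs[o]; Iss <- Iss[o]
  if (length(Vs) < 5)
    warning("rectifier fit with fewer than 5 voltages is poorly constrained")
  sgn <- sign(Iss)
  cross <- which(sgn[-length(sgn)] * sgn[-1] < 0)
  if (!length(cross))
    stop("no reversal (sign change) of Iss within the voltage range; ",
         "E is unidentifiable", call. = FALSE)
  k <- cross[1]
  E0 <- Vs[k] - Iss[k] * (Vs[k + 1] - Vs[k]) / (Iss[k + 1] - Iss[k])
  w <- ifelse(abs(Vs - E0) < 10, 0.1, 1)
  c0 <- {
    ref <- which.max(abs(Vs - E0))
    Iss[ref] / (f_v(Vs[ref], E0, v0_init, v1_from_constraint(E0, v0_init)) *
                (Vs[ref] - E0))
  }
  resid <- function(par) {
    E <- par[1]; v0 <- par[2]; cc <- par[3]
    if (abs(E + 70) < 1e-6 || v0 <= 0) return(rep(1e6, length(Vs)))
    v1 <- v1_from_constraint(E, v0)
    sqrt(w) * (cc * f_v(Vs, E, v0, v1) * (Vs - E) - Iss)
  }
  fit <- minpack.lm::nls.lm(par = c(E0, v0_init, c0), fn = resid,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  E <- fit$par[1]; v0 <- fit$par[2]
  list(E = E, v0 = v0, v1 = v1_from_constraint(E, v0), c = fit$par[3],
       residual_norm = sqrt(sum(resid(fit$par)^2)), E_crossing = E0)
}

#' Conductance scale from a peak current
#'
#' Inverts the current equation at the maximal-flux peak:
#' \eqn{g_0 = I_p / (f_{open} \, f_v(v) \, (v - E) \times 10^{-6})}.
#' \code{f_open} is the maximal photocycle factor reached in a forward
#' simulation at the data's maximal flux; before the kinetic stages have
#' run, a conservative occupancy constant (typically 0.8 for wild-type
#' ChR2) is used instead.
#'
#' @param Ip Peak current at maximal flux, nA (signed).
#' @param v Clamp voltage of that trial, mV.
#' @param E,v0,v1 Rectification parameters.
#' @param f_open_max Maximal simulated photocycle factor, or \code{NULL}
#'   to use the fallback constant.
#' @param fallback_open_frac Fallback occupancy (default 0.8).
#' @return g0 in pS.
#' @export
fit_conductance <- function(Ip, v, E, v0, v1, f_open_max = NULL,
                            fallback_open_frac = 0.8) {
  if (abs(v - E) < 1e-9)
    stop("trial voltage equals the reversal potential; unusable for g0",
         call. = FALSE)
  fom <- if (is.null(f_open_max)) fallback_open_frac else f_open_max
  g0 <- Ip / (fom * f_v(v, E, v0, v1) * (v - E) * 1e-6)
  if (!is.finite(g0) || g0 <= 0)
    stop("conductance estimate is not positive", call. = FALSE)
  g0
}

#' Dark recovery rate from second-pulse peaks
#'
#' Fits the peak-recovery exponential
#' \eqn{I_{peak}(t) = I_{peak0} - a e^{-G_{r0} t}} to second-pulse peaks
#' (times measured from the first pulse's offset), by nonlinear least
#' squares with \code{a} free. IPIs below \code{min_ipi} are excluded:
#' very short intervals are distorted by the faster transitions.
#'
#' @param t_p Peak times since first-pulse offset, ms.
#' @param I_p Peak currents, nA.
#' @param min_ipi Exclusion threshold, ms (default 100).
#' @return List with \code{Gr0} (ms^-1), \code{Ipeak0}, \code{a},
#'   \code{identifiable} and \code{n_used}.
#' @export
fit_peak_recovery <- function(t_p, I_p, min_ipi = 100) {
  keep <- t_p >= min_ipi
  t_p <- t_p[keep]; I_p <- I_p[keep]
  if (length(t_p) < 3)
    stop("need >= 3 usable IPIs after excluding t < ", min_ipi, " ms",
         call. = FALSE)
  if (diff(range(I_p)) < 1e-9 * max(1, abs(mean(I_p))))
    return(list(Gr0 = NA_real_, Ipeak0 = mean(I_p), a = 0,
                identifiable = FALSE, n_used = length(t_p)))
  # variable-projection grid for the rate, then full nonlinear polish
  grid <- 10^seq(-5, -2, length.out = 40)
  best <- NULL
  for (G in grid) {
    X <- cbind(1, exp(-G * t_p))
    cf <- stats::coef(stats::lm.fit(X, I_p))
    rss <- sum((I_p - X %*% cf)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(G = G, Ipeak0 = cf[1], a = -cf[2], rss = rss)
  }
  resid <- function(par)
    par[1] - par[2] * exp(-exp(par[3]) * t_p) - I_p
  fit <- minpack.lm::nls.lm(par = c(best$Ipeak0, best$a, log(best$G)),
                            fn = resid,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  list(Gr0 = unname(exp(fit$par[3])), Ipeak0 = unname(fit$par[1]),
       a = unname(fit$par[2]), identifiable = TRUE, n_used = length(t_p),
       residual_norm = sqrt(sum(resid(fit$par)^2)))
}

#' Biexponential decay fit
#'
#' Fits \eqn{I(t) = I_{slow} e^{-G_{slow} t} + I_{fast} e^{-G_{fast} t}}
#' with \eqn{G_{fast} \ge G_{slow} > 0}. Amplitudes are solved linearly
#' for each candidate rate pair (variable projection); rates are refined
#' from a fixed log-spaced 3-point multi-start to dodge local minima, ties
#' broken by lowest residual then lowest \code{G_fast}.
#'
#' @param t Times since decay onset, ms (first value 0).
#' @param I Currents, nA.
#' @return List with \code{I_slow, I_fast, G_slow, G_fast, rss}.
#' @export
fit_biexponential <- function(t, I) {
  stopifnot(length(t) >= 20, length(t) == length(I))
  Tspan <- max(t) - min(t)
  starts <- list(c(1, 20) / Tspan, c(4, 80) / Tspan, c(0.3, 6) / Tspan)
  amps_for <- function(Gs, Gf) {
    X <- cbind(exp(-Gs * t), exp(-Gf * t))
    cf <- tryCatch(stats::coef(stats::lm.fit(X, I)),
                   error = function(e) c(NA, NA))
    list(cf = cf, rss = if (anyNA(cf)) Inf else sum((I - X %*% cf)^2))
  }
  resid <- function(par) {
    Gs <- exp(par[1]); Gf <- Gs * (1 + exp(par[2]))
    a <- amps_for(Gs, Gf)
    if (!is.finite(a$rss)) return(rep(1e6, length(t)))
    I - cbind(exp(-Gs * t), exp(-Gf * t)) %*% a$cf
  }
  best <- NULL
  for (s in starts) {
    par0 <- c(log(s[1]), log(s[2] / s[1] - 1))
    fit <- tryCatch(minpack.lm::nls.lm(par = par0, fn = resid,
      control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-14,
                                           ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    Gs <- exp(fit$par[1]); Gf <- Gs * (1 + exp(fit$par[2]))
    a <- amps_for(Gs, Gf)
    cand <- list(G_slow = Gs, G_fast = Gf, I_slow = a$cf[1],
                 I_fast = a$cf[2], rss = a$rss)
    if (is.null(best) || cand$rss < best$rss - 1e-15 ||
        (abs(cand$rss - best$rss) <= 1e-15 && cand$G_fast < best$G_fast))
      best <- cand
  }
  if (is.null(best)) stop("biexponential fit failed", call. = FALSE)
  best
}

#' Amplitude-weighted collapse of biexponential rates
#'
#' Collapses N per-trial biexponential decays to the single effective
#' rate used by the 3-state model:
#' \deqn{G_d = \frac{1}{N}\sum_n \frac{I^n_{slow} G^n_{d1} +
#'   I^n_{fast} G^n_{d2}}{I^n_{slow} + I^n_{fast}}.}
#'
#' @param fits List of [fit_biexponential()] results.
#' @return Effective decay rate, ms^-1.
#' @export
effective_decay_rate <- function(fits) {
  vals <- vapply(fits, function(f)
    (f$I_slow * f$G_slow + f$I_fast * f$G_fast) / (f$I_slow + f$I_fast),
    numeric(1))
  mean(vals)
}

#' Off-curve (deactivation) fitting
#'
#' Fits each trial's off-phase with a biexponential decay. For the
#' 3-state model the two rates collapse to a single \code{Gd} via
#' [effective_decay_rate()]. For the 4-/6-state models the fitted decay
#' rates are identified with the eigenvalues of the dark O1/O2 subsystem
#' \deqn{\begin{pmatrix} -(G_{d1}+G_{f0}) & G_{b0} \\ G_{f0} &
#'   -(G_{d2}+G_{b0}) \end{pmatrix},}
#' and \code{Gd1}/\code{Gd2} are solved from the trace/determinant
#' relations holding \code{Gf0}/\code{Gb0} at their current estimates
#' (those two are re-fit in the on-curve and refinement stages, where they
#' are identifiable).
#'
#' @param step_pd The flux-dependence \code{protocol_data}.
#' @param params Current parameter record (supplies Gf0/Gb0 and the model
#'   order).
#' @return For 3-state, list with \code{Gd}; otherwise list with
#'   \code{Gd1, Gd2, Gf0, Gb0}; both carry \code{per_trial} fits and an
#'   \code{excluded} count.
#' @export
fit_off_curves <- function(step_pd, params) {
  order <- params$model_order
  fits <- list(); excluded <- 0L; weights <- numeric(0)
  for (pc in step_pd$trials) {
    ph <- segment_phases(pc)[[1]]
    idx <- ph$off
    if (length(idx) < 20) { excluded <- excluded + 1L; next }
    t0 <- pc$t[idx] - pc$t[idx[1]]
    I0 <- pc$I[idx]
    if (max(abs(I0)) > abs(I0[1]) * 1.05 + 1e-12) {
      warning("off segment not decaying; trial excluded")
      excluded <- excluded + 1L
      next
    }
    if (max(abs(I0)) < 1e-9) { excluded <- excluded + 1L; next }
    fits[[length(fits) + 1L]] <- fit_biexponential(t0, I0)
    weights <- c(weights, abs(I0[1]))
  }
  if (!length(fits))
    stop("no usable off segments", call. = FALSE)
  if (order == 3L)
    return(list(Gd = effective_decay_rate(fits), per_trial = fits,
                excluded = excluded))
  lam_s <- sum(vapply(fits, `[[`, numeric(1), "G_slow") * weights) / sum(weights)
  lam_f <- sum(vapply(fits, `[[`, numeric(1), "G_fast") * weights) / sum(weights)
  S <- lam_s + lam_f                       # = Gd1+Gf0 + Gd2+Gb0
  ab <- lam_s * lam_f + params$Gf0 * params$Gb0
  disc <- S^2 - 4 * ab
  clipped <- FALSE
  if (disc < 0) { disc <- 0; clipped <- TRUE }
  a <- (S + sqrt(disc)) / 2; b <- S - a
  Gd1 <- a - params$Gf0; Gd2 <- b - params$Gb0
  if (Gd1 <= 0) { Gd1 <- 0.5 * a; clipped <- TRUE }
  if (Gd2 <= 0) { Gd2 <- 0.5 * b; clipped <- TRUE }
  list(Gd1 = Gd1, Gd2 = Gd2, Gf0 = params$Gf0, Gb0 = params$Gb0,
       eigenvalues = c(slow = lam_s, fast = lam_f),
       per_trial = fits, excluded = excluded, clipped = clipped)
}

# sub-sample peak time via a parabola through the three samples around
# the discrete maximum of |I|
.peak_time_interp <- function(t, I) {
  j <- which.max(abs(I))
  if (j <= 1 || j >= length(I)) return(t[j])
  y <- abs(I[(j - 1):(j + 1)])
  denom <- y[1] - 2 * y[2] + y[3]
  if (abs(denom) < 1e-300) return(t[j])
  delta <- 0.5 * (y[1] - y[3]) / denom
  t[j] + delta * (t[j + 1] - t[j])
}

#' Opsin activation rates from short-pulse peak lag
#'
#' For the 6-state model only. The extra intermediate states delay the
#' current peak past the pulse offset; the observed lag identifies
#' \code{Go1}. The routine measures the mean peak lag over trials with
#' pulse width <= 3 ms, then root-finds the \code{Go1} (with
#' \code{Go2 = Go1}) whose simulated lag matches it. \code{Go2} is
#' subsequently refined jointly in later stages — a single-pulse protocol
#' constrains it only weakly.
#'
#' @param short_pd A shortPulse \code{protocol_data}.
#' @param params Current parameter record (6-state).
#' @param go_range Root-finding interval for the activation rate, ms^-1.
#' @return List with \code{Go1}, \code{Go2}, \code{observed_lag} (ms) and
#'   \code{at_bound} (TRUE when the lag is unresolvably small and the
#'   rates are set to their upper bound).
#' @export
fit_activation_rates <- function(short_pd, params,
                                 go_range = c(0.05, 100)) {
  stopifnot(params$model_order == 6L)
  sel <- which(vapply(short_pd$trials, function(pc)
    diff(pc$pulses[1, ]) <= 3, logical(1)))
  if (!length(sel))
    stop("need at least one short-pulse trial with width <= 3 ms",
         call. = FALSE)
  obs_lag <- mean(vapply(short_pd$trials[sel], function(pc) {
    i0 <- which(pc$t >= pc$pulses[1, 1] - 1e-9)
    .peak_time_interp(pc$t[i0], pc$I[i0]) - pc$pulses[1, 2]
  }, numeric(1)))
  dt <- stats::median(diff(short_pd$trials[[sel[1]]]$t))
  if (obs_lag <= dt / 2)
    return(list(Go1 = go_range[2], Go2 = go_range[2],
                observed_lag = obs_lag, at_bound = TRUE))
  model_lag <- function(go) {
    p <- params; p$Go1 <- go; p$Go2 <- go
    lags <- vapply(short_pd$trials[sel], function(pc) {
      sched <- .trial_schedule(pc)
      S <- .sim_states_fast(p, sched$edges, sched$fluxes, pc$t)
      I <- photocurrent_of_state(p, S, pc$V)
      i0 <- which(pc$t >= pc$pulses[1, 1] - 1e-9)
      .peak_time_interp(pc$t[i0], I[i0]) - pc$pulses[1, 2]
    }, numeric(1))
    mean(lags)
  }
  f <- function(lg) model_lag(exp(lg)) - obs_lag
  flo <- f(log(go_range[1])); fhi <- f(log(go_range[2]))
  if (flo * fhi > 0) {
    go <- if (abs(flo) < abs(fhi)) go_range[1] else go_range[2]
    return(list(Go1 = go, Go2 = go, observed_lag = obs_lag,
                at_bound = TRUE))
  }
  root <- stats::uniroot(f, lower = log(go_range[1]),
                         upper = log(go_range[2]), tol = 1e-6)
  go <- exp(root$root)
  list(Go1 = go, Go2 = go, observed_lag = obs_lag, at_bound = FALSE)
}

.free_on_curve <- function(order, single_flux, config) {
  free <- switch(as.character(order),
    "3" = c("ka", "kr", "p", "q", "phi_m"),
    "4" = ,
    "6" = c("k1", "k2", "p", "q", "phi_m", "kf", "kb", "Gf0", "Gb0",
            "gamma"))
  if (single_flux) free <- setdiff(free, c("phi_m", "p", "q"))
  setdiff(free, config$fixed)
}

#' On-curve stage: fit the remaining (light-dependence) parameters
#'
#' Minimizes the summed squared residual between simulated and observed
#' on-phase currents jointly over every flux level, simulating each trial
#' from the dark ground state. Parameters fixed by earlier stages are held
#' fixed; the conductance scale is re-derived at each evaluation by peak
#' matching at the maximal flux. With a single flux level the
#' flux-dependence parameters (\code{phi_m}, \code{p}, \code{q}) are
#' auto-fixed to their initial values.
#'
#' For the 6-state model the activation rates are released here too
#' (initialized from the short-pulse lag estimate) unless
#' \code{free_go = FALSE}.
#'
#' @param step_pd Flux-dependence \code{protocol_data}.
#' @param params Parameter record carrying earlier-stage values.
#' @param config A [fit_config()].
#' @param free_go Release Go1/Go2 alongside the light parameters
#'   (6-state; set FALSE when no short-pulse data exist).
#' @return List with updated \code{params}, \code{free} names, optimizer
#'   diagnostics and the auto-fix flag.
#' @export
fit_on_curves <- function(step_pd, params, config = fit_config(),
                          free_go = TRUE) {
  single_flux <- length(unique(step_pd$phis)) == 1L
  free <- .free_on_curve(params$model_order, single_flux, config)
  if (params$model_order == 6L && free_go)
    free <- unique(c(free, setdiff(c("Go1", "Go2"), config$fixed)))
  trials <- .prep_trials(step_pd, "on", config$plateau)
  phi_ref <- exp(mean(log(vapply(trials, `[[`, numeric(1), "phi"))))
  go_tight <- intersect(free, c("Go1", "Go2"))
  bounds <- .coord_bounds(config, free, params = params,
                          tight = go_tight, frac = config$refine_bounds)
  obj <- .make_objective(trials, params, free, bounds, phi_ref)
  z0 <- .pack_box(params, free, bounds, phi_ref)
  res <- .run_box_optim(obj, z0, config$maxit_on)
  out <- .unpack_box(params, free, bounds, res$par, phi_ref)
  # conductance correction with the fitted kinetics
  out$g0 <- .g0_peak_match(out, trials)
  list(params = out, free = free, objective = res$value,
       evaluations = res$counts, iterations = res$iterations,
       converged = res$converged, flux_params_fixed = single_flux)
}

#' Joint post-fit refinement over the entire data set
#'
#' Optional second optimization phase: all non-fixed kinetic parameters
#' are re-optimized simultaneously over every supplied photocurrent (full
#' on- and off-phases), with the dark and activation parameters bounded
#' to \code{refine_bounds} (default 50--200\%) of their stage-1 values.
#' The result never increases the total residual: if the joint
#' optimization ends worse it falls back to the stage-1 values.
#'
#' @param pds List of \code{protocol_data} sets to refine over (typically
#'   step plus shortPulse).
#' @param params Stage-1 parameter record.
#' @param config A [fit_config()].
#' @param extra_free Additional parameter names to release (e.g. the
#'   activation rates when a shortPulse set is present).
#' @return As [fit_on_curves()], plus \code{fell_back}.
#' @export
post_fit_refinement <- function(pds, params, config = fit_config(),
                                extra_free = character()) {
  if (!config$refine)
    return(list(params = params, refined = FALSE, fell_back = FALSE))
  single_flux <- length(unique(pds[[1]]$phis)) == 1L
  dark <- switch(as.character(params$model_order),
                 "3" = "Gd", c("Gd1", "Gd2", "Gf0", "Gb0"))
  free <- unique(c(.free_on_curve(params$model_order, single_flux, config),
                   dark, extra_free))
  free <- setdiff(free, config$fixed)
  trials <- do.call(c, lapply(pds, .prep_trials, idx_mode = "all",
                              plateau = config$plateau))
  phi_ref <- exp(mean(log(vapply(trials, `[[`, numeric(1), "phi"))))
  tight <- intersect(free, c(dark, c("Go1", "Go2")))
  bounds <- .coord_bounds(config, free, params = params, tight = tight,
                          frac = config$refine_bounds)
  obj <- .make_objective(trials, params, free, bounds, phi_ref)
  z0 <- .pack_box(params, free, bounds, phi_ref)
  f0 <- obj(z0)
  res <- .run_box_optim(obj, z0, config$maxit_refine)
  fell_back <- res$value > f0
  out <- if (fell_back) params
         else .unpack_box(params, free, bounds, res$par, phi_ref)
  out$g0 <- .g0_peak_match(out, trials)
  list(params = out, free = free, objective = min(res$value, f0),
       objective_stage1 = f0, evaluations = res$counts,
       iterations = res$iterations, refined = TRUE, fell_back = fell_back)
}

#' Staged characterization pipeline
#'
#' Orchestrates the full fitting algorithm over a keyed data set of
#' characterization protocols: voltage rectification (E, v0, v1), initial
#' conductance estimate, dark recovery (Gr0), off-curve deactivation
#' rates, short-pulse activation rates (6-state), on-curve optimization of
#' the light-dependence parameters, conductance correction, and the
#' optional joint refinement. Stages whose protocol is absent are skipped
#' and their parameters kept at the initial values (the flux-dependence
#' \code{"step"} set is the required minimal set). The whole run is
#' deterministic for a given data set and configuration.
#'
#' @param dataset Named list of \code{protocol_data} sets; recognized keys
#'   \code{"step"}, \code{"rectifier"}, \code{"recovery"},
#'   \code{"shortPulse"}.
#' @param model_order 3, 4 or 6.
#' @param initial Initial parameter record (default [initial_params()]).
#' @param config A [fit_config()].
#' @return Object of class \code{fit_result}: \code{$params} (the fitted
#'   record), \code{$stages} (per-stage diagnostics), \code{$skipped}
#'   (stage names skipped for missing data) and \code{$flags}.
#' @export
fit_models <- function(dataset, model_order = 6,
                       initial = initial_params(model_order),
                       config = fit_config(model_order)) {
  if (!length(dataset) || is.null(dataset$step))
    stop('dataset must contain the flux-dependence ("step") protocol — ',
         "the minimal set", call. = FALSE)
  params <- initial
  stopifnot(params$model_order == model_order)
  stages <- list(); skipped <- character(); flags <- list()

  if (!is.null(dataset$rectifier)) {
    rp <- dataset$rectifier
    Vs <- rp$index$V
    Iss <- vapply(rp$trials, function(pc)
      find_steady_state(pc, config = config$plateau)$value, numeric(1))
    rec <- fit_rectifier(Vs, Iss)
    params$E <- rec$E; params$v0 <- rec$v0; params$v1 <- rec$v1
    stages$rectifier <- rec
  } else skipped <- c(skipped, "rectifier")

  # initial conductance from the maximal-flux peak (fallback occupancy)
  imax <- which.max(dataset$step$index$phi)
  pk <- find_peak(dataset$step$trials[[imax]])
  Vmax <- dataset$step$index$V[imax]
  params$g0 <- fit_conductance(pk$value, Vmax, params$E, params$v0,
                               params$v1,
                               fallback_open_frac = config$fallback_open_frac)
  stages$conductance_initial <- list(g0 = params$g0, fallback = TRUE)

  if (!is.null(dataset$recovery)) {
    al <- align_peaks_to_first_offset(dataset$recovery)
    rec <- fit_peak_recovery(al$t_p, al$I_p, min_ipi = config$min_ipi)
    if (isTRUE(rec$identifiable)) params$Gr0 <- rec$Gr0
    else flags$Gr0_unidentifiable <- TRUE
    stages$recovery <- rec
  } else skipped <- c(skipped, "recovery")

  off <- fit_off_curves(dataset$step, params)
  if (model_order == 3L) params$Gd <- off$Gd
  else { params$Gd1 <- off$Gd1; params$Gd2 <- off$Gd2 }
  stages$off_curves <- off

  if (model_order == 6L) {
    if (!is.null(dataset$shortPulse)) {
      act <- fit_activation_rates(dataset$shortPulse, params)
      params$Go1 <- act$Go1; params$Go2 <- act$Go2
      if (act$at_bound) flags$Go_at_bound <- TRUE
      stages$activation <- act
    } else skipped <- c(skipped, "shortPulse")
  }

  on <- fit_on_curves(dataset$step, params, config,
                      free_go = !is.null(dataset$shortPulse))
  params <- on$params
  stages$on_curves <- on[setdiff(names(on), "params")]
  flags$g0_corrected <- TRUE

  go_free <- if (model_order == 6L && !is.null(dataset$shortPulse))
    c("Go1", "Go2") else character()
  ref_pds <- Filter(Negate(is.null), dataset[c("step", "shortPulse")])
  ref <- post_fit_refinement(ref_pds, params, config,
                             extra_free = go_free)
  params <- ref$params
  stages$refinement <- ref[setdiff(names(ref), "params")]

  structure(list(params = params, stages = stages, skipped = skipped,
                 flags = flags, model_order = model_order),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: %d-state model\n", x$model_order))
  if (length(x$skipped))
    cat("  stages skipped (missing data):",
        paste(x$skipped, collapse = ", "), "\n")
  if (!is.null(x$stages$refinement$objective))
    cat(sprintf("  final objective: %.4g (refinement %s)\n",
                x$stages$refinement$objective,
                if (isTRUE(x$stages$refinement$fell_back)) "fell back"
                else "accepted"))
  print(x$params)
  invisible(x)
}

#' Per-trial residual diagnostics for a fitted model
#'
#' Re-simulates every trial of a data set under the fitted parameters and
#' reports the maximum absolute residual as a percentage of each trial's
#' steady-state current. Trials that never reach a plateau (short pulses)
#' are normalized by the model's steady-state current at their flux and
#' voltage.
#'
#' @param params Fitted [opsin_params()].
#' @param dataset Named list of \code{protocol_data} sets.
#' @return Data frame with one row per trial: protocol, phi, V, max
#'   absolute residual (nA), the normalizing |Iss| and the percentage.
#' @export
residual_diagnostics <- function(params, dataset) {
  rows <- list()
  for (proto in names(dataset)) {
    pd <- dataset[[proto]]
    for (i in seq_along(pd$trials)) {
      pc <- pd$trials[[i]]
      sched <- .trial_schedule(pc)
      S <- .sim_states_fast(params, sched$edges, sched$fluxes, pc$t)
      I_model <- photocurrent_of_state(params, S, pc$V)
      resid <- max(abs(I_model - pc$I))
      ss <- find_steady_state(pc)
      Iss <- if (is.finite(ss$value) && ss$at_plateau) abs(ss$value)
      else abs(photocurrent_of_state(
        params, steady_state(params, pc$phi), pc$V))
      rows[[length(rows) + 1L]] <- data.frame(
        protocol = proto, run = pd$index$run[i], phi = pc$phi, V = pc$V,
        max_resid_nA = resid, Iss_nA = Iss,
        max_resid_pct = 100 * resid / Iss)
    }
  }
  do.call(rbind, rows)
}
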