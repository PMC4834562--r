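#' Plateau-detector configuration constants
#'
#' The steady-state (plateau) detector averages the final
#' \code{window_frac} of the on-phase and accepts the value only if a
#' straight-line fit over that window has a slope below
#' \code{slope_frac} of |mean| per 100 ms. These are named constants, not
#' magic numbers; pass modified copies to [find_steady_state()].
#'
#' @export
plateau_config <- function(window_frac = 0.1, slope_frac = 0.01,
                           min_samples = 50L) {
  list(window_frac = window_frac, slope_frac = slope_frac,
       min_samples = as.integer(min_samples))
}

#' A voltage-clamped photocurrent trace
#'
#' The central data object: one recorded or simulated photocurrent with
#' its pulse annotations. Derived features (peak, plateau, phase indices)
#' are pure functions of the stored arrays, computed on demand by
#' [find_peak()], [find_steady_state()] and [segment_phases()].
#'
#' @param I Current array, nA.
#' @param t Time array in ms, strictly increasing, or a scalar time-step
#'   (expanded to \code{(0:(n-1)) * t}).
#' @param pulses n x 2 matrix (or nested list) of pulse on/off times, ms;
#'   every pulse must lie inside the recorded interval.
#' @param phi Stimulating photon flux, photons mm^-2 s^-1.
#' @param V Clamp voltage in mV, or \code{NA} for unclamped recordings.
#' @param states Optional state-occupancy trajectory (rows matching
#'   \code{t}) from a simulation.
#' @return Object of class \code{photocurrent}.
#' @export
photocurrent <- function(I, t, pulses, phi, V = NA_real_, states = NULL) {
  if (length(t) == 1L) t <- (seq_along(I) - 1) * t
  if (length(t) != length(I))
    stop("t and I must have the same length", call. = FALSE)
  if (any(diff(t) <= 0))
    stop("t must be strictly increasing", call. = FALSE)
  if (is.list(pulses)) pulses <- do.call(rbind, lapply(pulses, as.numeric))
  pulses <- matrix(as.numeric(pulses), ncol = 2)
  if (nrow(pulses)) {
    if (any(pulses[, 2] <= pulses[, 1]))
      stop("pulse off-times must exceed on-times", call. = FALSE)
    if (any(pulses < t[1] - 1e-9) || any(pulses > t[length(t)] + 1e-9))
      stop("pulses must lie inside the recorded interval", call. = FALSE)
    if (nrow(pulses) > 1 &&
        any(pulses[-1, 1] < pulses[-nrow(pulses), 2]))
      stop("pulses must be ordered and non-overlapping", call. = FALSE)
  }
  structure(list(t = as.numeric(t), I = as.numeric(I), pulses = pulses,
                 phi = phi, V = V, states = states),
            class = "photocurrent")
}

#' @export
print.photocurrent <- function(x, ...) {
  cat(sprintf(
    "photocurrent: %d samples over %.4g ms, %d pulse(s), phi = %.3g, V = %s\n",
    length(x$t), diff(range(x$t)), nrow(x$pulses), x$phi,
    if (is.na(x$V)) "unclamped" else paste0(x$V, " mV")))
  if (nrow(x$pulses)) {
    pk <- find_peak(x)
    cat(sprintf("  peak %.4g nA at %.4g ms\n", pk$value, pk$time))
  }
  invisible(x)
}

#' Peak photocurrent
#'
#' Global extremum of |I| at or after the first pulse onset, sign
#' preserved; ties resolve to the earliest sample.
#'
#' @param pc A [photocurrent()].
#' @param from_pulse Search from this pulse's onset (default 1).
#' @return List with \code{value} (nA), \code{time} (ms), \code{index}.
#' @export
find_peak <- function(pc, from_pulse = 1L) {
  stopifnot(inherits(pc, "photocurrent"))
  if (!nrow(pc$pulses)) stop("photocurrent has no pulses", call. = FALSE)
  if (!length(pc$I)) stop("empty trace", call. = FALSE)
  i0 <- which(pc$t >= pc$pulses[from_pulse, 1] - 1e-9)[1]
  if (is.na(i0)) stop("no samples at/after pulse onset", call. = FALSE)
  seg <- abs(pc$I[i0:length(pc$I)])
  j <- which.max(seg)  # which.max returns the first maximum (earliest tie)
  idx <- i0 + j - 1
  list(value = pc$I[idx], time = pc$t[idx], index = idx)
}

#' Steady-state (plateau) current
#'
#' Mean of the final fraction of a pulse's on-phase, accepted only when a
#' straight-line fit over that window is flat: |slope| below
#' \code{slope_frac} of |mean| per 100 ms. Short or still-ramping
#' on-phases are flagged \code{at_plateau = FALSE}.
#'
#' @param pc A [photocurrent()].
#' @param pulse Pulse index (default 1).
#' @param config See [plateau_config()].
#' @return List with \code{value} (nA) and \code{at_plateau} (logical).
#' @export
find_steady_state <- function(pc, pulse = 1L, config = plateau_config()) {
  stopifnot(inherits(pc, "photocurrent"))
  on <- pc$pulses[pulse, 1]; off <- pc$pulses[pulse, 2]
  idx <- which(pc$t >= on - 1e-9 & pc$t < off - 1e-9)
  if (length(idx) < config$min_samples)
    return(list(value = NA_real_, at_plateau = FALSE))
  nwin <- max(2L, ceiling(config$window_frac * length(idx)))
  win <- idx[(length(idx) - nwin + 1):length(idx)]
  m <- mean(pc$I[win])
  slope <- unname(stats::coef(stats::lm.fit(
    cbind(1, pc$t[win] - pc$t[win[1]]), pc$I[win]))[2])
  ok <- is.finite(slope) && abs(slope) < config$slope_frac * abs(m) / 100
  list(value = m, at_plateau = ok)
}

#' On/off phase index ranges per pulse
#'
#' Half-open index ranges aligned to the pulse times: the on-range of
#' pulse k covers \code{[t_on, t_off)}, its off-range runs from
#' \code{t_off} to the next pulse's onset (or the trace end for the last
#' pulse). Together the ranges partition the post-onset trace.
#'
#' @param pc A [photocurrent()].
#' @return List (one element per pulse) of lists with integer index
#'   vectors \code{on} and \code{off}.
#' @export
segment_phases <- function(pc) {
  stopifnot(inherits(pc, "photocurrent"))
  np <- nrow(pc$pulses)
  if (!np) return(list())
  lapply(seq_len(np), function(k) {
    on_k <- pc$pulses[k, 1]; off_k <- pc$pulses[k, 2]
    next_on <- if (k < np) pc$pulses[k + 1, 1] else Inf
    on_idx <- which(pc$t >= on_k - 1e-9 & pc$t < off_k - 1e-9)
    off_idx <- which(pc$t >= off_k - 1e-9 & pc$t < next_on - 1e-9)
    list(on = on_idx, off = off_idx)
  })
}

#' A keyed collection of photocurrents for one protocol
#'
#' Trials are indexed by (run, flux, voltage); each added trial's
#' annotations must match a grid position.
#'
#' @param protocol Protocol name.
#' @param n_runs Number of runs (e.g. IPIs or pulse durations).
#' @param phis Flux levels of the grid.
#' @param Vs Voltage levels of the grid.
#' @return Object of class \code{protocol_data}.
#' @export
protocol_data <- function(protocol, n_runs = 1L, phis, Vs) {
  structure(list(protocol = protocol, n_runs = as.integer(n_runs),
                 phis = as.numeric(phis), Vs = as.numeric(Vs),
                 trials = list(),
                 index = data.frame(run = integer(), phi = numeric(),
                                    V = numeric())),
            class = "protocol_data")
}

#' @export
print.protocol_data <- function(x, ...) {
  cat(sprintf("protocol_data '%s': %d/%d trial(s) on a %d x %d x %d grid\n",
              x$protocol, length(x$trials),
              x$n_runs * length(x$phis) * length(x$Vs),
              x$n_runs, length(x$phis), length(x$Vs)))
  invisible(x)
}

.match_level <- function(x, levels) {
  i <- which(abs(levels - x) <= 1e-9 * pmax(1, abs(levels)))
  if (length(i) != 1L) NA_integer_ else i
}

#' @rdname protocol_data
#' @param pd A \code{protocol_data} object.
#' @param pc A [photocurrent()] whose \code{phi}/\code{V} annotations sit
#'   on the grid.
#' @param run Run index of the trial.
#' @export
add_trial <- function(pd, pc, run = 1L) {
  stopifnot(inherits(pd, "protocol_data"), inherits(pc, "photocurrent"))
  if (run < 1 || run > pd$n_runs) stop("run out of range", call. = FALSE)
  if (is.na(.match_level(pc$phi, pd$phis)))
    stop("trial phi ", pc$phi, " is not on the protocol grid", call. = FALSE)
  if (is.na(.match_level(pc$V, pd$Vs)))
    stop("trial V ", pc$V, " is not on the protocol grid", call. = FALSE)
  pd$trials[[length(pd$trials) + 1L]] <- pc
  pd$index <- rbind(pd$index,
                    data.frame(run = as.integer(run), phi = pc$phi, V = pc$V))
  pd
}

#' @rdname protocol_data
#' @param phi,V Grid values identifying the trial.
#' @export
get_trial <- function(pd, run = 1L, phi = pd$phis[1], V = pd$Vs[1]) {
  hit <- which(pd$index$run == run &
               abs(pd$index$phi - phi) <= 1e-9 * pmax(1, abs(phi)) &
               abs(pd$index$V - V) <= 1e-9 * pmax(1, abs(V)))
  if (length(hit) != 1L) stop("trial not found", call. = FALSE)
  pd$trials[[hit]]
}

#' Second-pulse peaks aligned to the first pulse offset
#'
#' For a recovery-protocol data set, extracts each trial's second-pulse
#' peak with time measured from the first pulse's offset — the abscissa of
#' the peak-recovery exponential fit.
#'
#' @param pd A recovery \code{protocol_data} (every trial needs >= 2
#'   pulses).
#' @return List with \code{t_p} (ms since first offset), \code{I_p} (nA),
#'   ordered as the trials were added.
#' @export
align_peaks_to_first_offset <- function(pd) {
  stopifnot(inherits(pd, "protocol_data"))
  t_p <- numeric(0); I_p <- numeric(0)
  for (pc in pd$trials) {
    if (nrow(pc$pulses) < 2)
      stop("recovery alignment needs >= 2 pulses per trial", call. = FALSE)
    pk <- find_peak(pc, from_pulse = 2L)
    t_p <- c(t_p, pk$time - pc$pulses[1, 2])
    I_p <- c(I_p, pk$value)
  }
  list(t_p = t_p, I_p = I_p)
}
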