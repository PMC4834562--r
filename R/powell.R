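#' Powell's conjugate-direction minimizer with box constraints
#'
#' Derivative-free minimization by successive one-dimensional line
#' searches (Brent's method via [stats::optimize()]) along an evolving
#' direction set, following Powell's classic update rule: after each sweep
#' the direction of largest single-step decrease may be replaced by the
#' sweep's net displacement. Bounds are honoured by clipping each line
#' search to the feasible interval along its direction. The routine is
#' fully deterministic.
#'
#' Callers should pre-scale parameters to comparable magnitudes (the
#' fitting pipeline works in a log-scaled unit box).
#'
#' @param fn Objective; takes a numeric vector, returns a scalar.
#' @param x0 Start point (inside the box).
#' @param lower,upper Bounds (vectors recycled to \code{length(x0)}).
#' @param maxit Maximum number of full direction-set sweeps.
#' @param reltol Relative convergence tolerance on the objective decrease
#'   per sweep.
#' @param ls_tol Absolute line-search tolerance (in the caller's scaled
#'   coordinates).
#' @return List with \code{par}, \code{value}, \code{counts} (function
#'   evaluations), \code{iterations} and \code{converged}.
#' @export
powell_minimize <- function(fn, x0, lower = -Inf, upper = Inf,
                            maxit = 200, reltol = 1e-12, ls_tol = 1e-7) {
  n <- length(x0)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  x <- pmin(pmax(x0, lower), upper)
  nev <- 0L
  f <- function(z) { nev <<- nev + 1L; fn(z) }
  fx <- f(x)
  dirs <- diag(n)

  line_min <- function(x, d, fx) {
    # feasible alpha interval along d
    a_lo <- -Inf; a_hi <- Inf
    for (i in seq_len(n)) {
      if (d[i] > 0) {
        a_lo <- max(a_lo, (lower[i] - x[i]) / d[i])
        a_hi <- min(a_hi, (upper[i] - x[i]) / d[i])
      } else if (d[i] < 0) {
        a_lo <- max(a_lo, (upper[i] - x[i]) / d[i])
        a_hi <- min(a_hi, (lower[i] - x[i]) / d[i])
      }
    }
    if (!is.finite(a_lo)) a_lo <- -1e3
    if (!is.finite(a_hi)) a_hi <- 1e3
    if (a_hi - a_lo < ls_tol) return(list(x = x, f = fx))
    opt <- stats::optimize(function(a) f(x + a * d),
                           interval = c(a_lo, a_hi), tol = ls_tol)
    if (opt$objective < fx)
      list(x = pmin(pmax(x + opt$minimum * d, lower), upper),
           f = opt$objective)
    else list(x = x, f = fx)
  }

  converged <- FALSE
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    x_start <- x; f_start <- fx
    biggest <- 0; ibig <- 0L
    for (i in seq_len(n)) {
      res <- line_min(x, dirs[, i], fx)
      if (fx - res$f > biggest) { biggest <- fx - res$f; ibig <- i }
      x <- res$x; fx <- res$f
    }
    if (2 * (f_start - fx) <= reltol * (abs(f_start) + abs(fx)) + 1e-300) {
      converged <- TRUE
      break
    }
    d_new <- x - x_start
    nrm <- sqrt(sum(d_new^2))
    if (nrm > 1e-14 && ibig > 0L) {
      d_new <- d_new / nrm
      xe <- pmin(pmax(x + (x - x_start), lower), upper)
      fe <- f(xe)
      if (fe < f_start) {
        tcrit <- 2 * (f_start - 2 * fx + fe) *
          (f_start - fx - biggest)^2 - biggest * (f_start - fe)^2
        if (tcrit < 0) {
          res <- line_min(x, d_new, fx)
          x <- res$x; fx <- res$f
          dirs[, ibig] <- dirs[, n]
          dirs[, n] <- d_new
        }
      }
    }
  }
  list(par = x, value = fx, counts = nev, iterations = it,
       converged = converged)
}
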