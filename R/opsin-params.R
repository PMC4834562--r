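#' Photocycle state names for each model order
#'
#' The state ordering is part of the public contract: trajectories, CSV
#' exports and the NMODL emitter all list states in this order.
#'
#' @param model_order 3, 4 or 6.
#' @return Character vector of state names.
#' @export
#' @examples
#' state_names(3)
#' state_names(6)
state_names <- function(model_order) {
  switch(as.character(model_order),
    "3" = c("C", "O", "D"),
    "4" = c("C1", "O1", "O2", "C2"),
    "6" = c("C1", "I1", "O1", "O2", "I2", "C2"),
    stop("model_order must be 3, 4 or 6", call. = FALSE)
  )
}

.param_fields <- function(model_order) {
  common <- c("g0", "phi_m", "p", "q", "Gr0", "E", "v0", "v1")
  switch(as.character(model_order),
    "3" = c("g0", "phi_m", "ka", "kr", "p", "q", "Gd", "Gr0", "E", "v0", "v1"),
    "4" = c("g0", "gamma", "phi_m", "k1", "k2", "p", "kf", "kb", "q",
            "Gf0", "Gb0", "Gd1", "Gd2", "Gr0", "E", "v0", "v1"),
    "6" = c("g0", "gamma", "phi_m", "k1", "k2", "p", "kf", "kb", "q",
            "Gf0", "Gb0", "Go1", "Go2", "Gd1", "Gd2", "Gr0", "E", "v0", "v1"),
    stop("model_order must be 3, 4 or 6", call. = FALSE)
  )
}

#' Construct an opsin parameter record
#'
#' Bundles every symbol of a 3-, 4- or 6-state Markov photocycle model of a
#' light-gated ion channel, together with the conductance and voltage
#' rectification parameters. Units are fixed package-wide: rates in
#' \eqn{ms^{-1}}, voltages in mV, conductance scale \code{g0} in pS (defined
#' at \eqn{v = -70} mV), flux half-saturation \code{phi_m} in photons
#' mm\eqn{^{-2}} s\eqn{^{-1}}.
#'
#' By default the rectification amplitude \code{v1} is tied to \code{E} and
#' \code{v0} through the normalization constraint \eqn{f_v(-70) = 1} (see
#' [v1_from_constraint()]); pass an explicit \code{v1} together with
#' \code{constrain_v1 = FALSE} to release it.
#'
#' @param model_order Number of photocycle states: 3, 4 or 6.
#' @param ... Named numeric parameter values; see Details for the fields of
#'   each model order.
#' @param constrain_v1 If \code{TRUE} (default), \code{v1} is computed from
#'   \code{E} and \code{v0} and any supplied value is checked against the
#'   constraint.
#'
#' @details Field sets: 3-state \code{g0, phi_m, ka, kr, p, q, Gd, Gr0, E,
#' v0, v1}; 4-state adds the second open state (\code{gamma, k1, k2, kf, kb,
#' Gf0, Gb0, Gd1, Gd2}) and drops \code{ka, kr, Gd}; 6-state additionally
#' has the activation rates \code{Go1, Go2} of the intermediate states.
#'
#' @return An object of class \code{opsin_params}: a named list of numeric
#'   values plus \code{model_order}.
#' @seealso [chr2_params()] for ready-made ChR2 values.
#' @export
opsin_params <- function(model_order, ..., constrain_v1 = TRUE) {
  model_order <- as.integer(model_order)
  fields <- .param_fields(model_order)
  vals <- list(...)
  if (length(vals) == 1L && is.list(vals[[1]]) && is.null(names(vals)))
    vals <- vals[[1]]
  unknown <- setdiff(names(vals), fields)
  if (length(unknown))
    stop("unknown parameter(s) for ", model_order, "-state model: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (constrain_v1 && !is.null(vals$E) && !is.null(vals$v0)) {
    v1c <- v1_from_constraint(vals$E, vals$v0)
    if (!is.null(vals$v1) &&
        abs(vals$v1 - v1c) > 1e-9 * max(1, abs(v1c)) &&
        abs(vals$v1 - v1c) > 5e-3 * abs(v1c)) {
      stop("supplied v1 (", vals$v1, ") violates the f_v(-70)=1 constraint (",
           signif(v1c, 8), "); use constrain_v1 = FALSE to release it",
           call. = FALSE)
    }
    vals$v1 <- v1c
  }
  missing <- setdiff(fields, names(vals))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  p <- structure(lapply(fields, function(f) as.numeric(vals[[f]])),
                 names = fields)
  p$model_order <- model_order
  p$constrain_v1 <- isTRUE(constrain_v1)
  class(p) <- "opsin_params"
  validate_opsin_params(p)
  p
}

#' Validate an opsin parameter record
#'
#' Checks positivity of every rate coefficient and of \code{phi_m}, the Hill
#' exponents, \eqn{0 \le \gamma \le 1}, \code{v0 != 0}, and (when active)
#' the \code{v1} constraint to relative tolerance 1e-9.
#'
#' @param p An \code{opsin_params} object.
#' @return \code{p}, invisibly; errors describe the first violated invariant.
#' @export
validate_opsin_params <- function(p) {
  stopifnot(inherits(p, "opsin_params"))
  rate_fields <- intersect(names(p),
    c("phi_m", "ka", "kr", "k1", "k2", "kf", "kb", "Go1", "Go2",
      "Gd", "Gd1", "Gd2"))
  for (f in rate_fields)
    if (!is.finite(p[[f]]) || p[[f]] <= 0)
      stop("parameter ", f, " must be strictly positive", call. = FALSE)
  for (f in intersect(names(p), c("Gf0", "Gb0", "Gr0")))
    if (!is.finite(p[[f]]) || p[[f]] < 0)
      stop("parameter ", f, " must be non-negative", call. = FALSE)
  if (p$p <= 0 || p$q <= 0)
    stop("Hill exponents p and q must be > 0", call. = FALSE)
  if (!is.null(p$gamma) && (p$gamma < 0 || p$gamma > 1))
    stop("gamma must lie in [0, 1]", call. = FALSE)
  if (p$g0 <= 0) stop("g0 must be strictly positive", call. = FALSE)
  if (p$v0 == 0) stop("v0 must be non-zero", call. = FALSE)
  if (isTRUE(p$constrain_v1)) {
    v1c <- v1_from_constraint(p$E, p$v0)
    if (abs(p$v1 - v1c) > 1e-9 * max(1, abs(v1c)))
      stop("v1 constraint violated: v1 = ", p$v1, ", constraint gives ", v1c,
           call. = FALSE)
  }
  invisible(p)
}

#' @export
print.opsin_params <- function(x, ...) {
  cat(sprintf("%d-state opsin model parameters\n", x$model_order))
  fields <- .param_fields(x$model_order)
  vals <- vapply(fields, function(f) x[[f]], numeric(1))
  df <- data.frame(value = signif(vals, 6), row.names = fields)
  print(df)
  cat(sprintf("v1 constraint (f_v(-70 mV) = 1): %s\n",
              if (isTRUE(x$constrain_v1)) "active" else "released"))
  invisible(x)
}

#' Rectification amplitude from the normalization constraint
#'
#' The voltage factor is defined to equal 1 at the reference holding
#' potential of \eqn{-70} mV. That pins the amplitude parameter:
#' \deqn{v_1 = \frac{70 + E}{e^{(70+E)/v_0} - 1}.}
#'
#' @param E Reversal potential, mV. Must not equal \eqn{-70} mV.
#' @param v0 Rectification shape parameter, mV (non-zero).
#' @return \code{v1} in mV, the unique value making \eqn{f_v(-70) = 1}.
#' @export
#' @examples
#' v1_from_constraint(0, 43)  # 17.1 mV, the ChR2 value
v1_from_constraint <- function(E, v0) {
  if (v0 == 0) stop("v0 must be non-zero", call. = FALSE)
  u <- 70 + E
  if (abs(u) < 1e-12)
    stop("E = -70 mV: v1 constraint undefined (f_v anchored at its own zero)",
         call. = FALSE)
  r <- u / v0
  # expm1 keeps precision when v0 is large (linear, non-rectifying regime)
  u / expm1(r)
}

#' ChR2 parameter fixtures
#'
#' Reference parameter sets for wild-type Channelrhodopsin-2. The 6-state
#' record holds the experimentally derived values used throughout the
#' package's verification-by-parameter-recovery procedure. The 3- and
#' 4-state records are package-derived companions: the 4-state set shares
#' the 6-state rates (it is the instantaneous-activation limit of the
#' 6-state scheme), while the 3-state set is a documented, self-generated
#' approximation with a single open state.
#'
#' @param model_order 3, 4 or 6.
#' @return An [opsin_params()] record.
#' @export
#' @examples
#' chr2_params(6)$g0   # 27600 pS
chr2_params <- function(model_order = 6) {
  model_order <- as.integer(model_order)
  if (model_order == 6) {
    opsin_params(6,
      g0 = 2.76e4, gamma = 8.33e-16, phi_m = 5.07e17,
      k1 = 18.5, k2 = 3.75, p = 0.982,
      Gf0 = 0.0365, kf = 0.121, Gb0 = 0.0146, kb = 0.133, q = 1.45,
      Go1 = 1.93, Go2 = 2.65, Gd1 = 0.108, Gd2 = 0.0111, Gr0 = 0.00033,
      E = 0, v0 = 43)
  } else if (model_order == 4) {
    opsin_params(4,
      g0 = 2.76e4, gamma = 8.33e-16, phi_m = 5.07e17,
      k1 = 18.5, k2 = 3.75, p = 0.982,
      Gf0 = 0.0365, kf = 0.121, Gb0 = 0.0146, kb = 0.133, q = 1.45,
      Gd1 = 0.108, Gd2 = 0.0111, Gr0 = 0.00033,
      E = 0, v0 = 43)
  } else if (model_order == 3) {
    # self-generated single-open-state approximation (synthetic companion
    # set, not an experimentally tabulated record)
    opsin_params(3,
      g0 = 2.76e4, phi_m = 5.07e17,
      ka = 5, kr = 0.1, p = 0.982, q = 1.45,
      Gd = 0.0909, Gr0 = 0.00033,
      E = 0, v0 = 43)
  } else stop("model_order must be 3, 4 or 6", call. = FALSE)
}

#' Default initial guesses for fitting
#'
#' A deliberately rough starting record for the staged fitting pipeline,
#' suitable for wild-type ChR2-like photocurrents.
#'
#' @param model_order 3, 4 or 6.
#' @return An [opsin_params()] record.
#' @export
initial_params <- function(model_order = 6) {
  model_order <- as.integer(model_order)
  if (model_order == 3) {
    opsin_params(3, g0 = 2.5e4, phi_m = 3.5e17, ka = 4, kr = 0.05,
                 p = 1, q = 1, Gd = 0.1, Gr0 = 0.00033, E = 0, v0 = 43)
  } else {
    common <- list(g0 = 2.5e4, gamma = 0.05, phi_m = 3.5e17,
                   k1 = 10, k2 = 3, p = 1,
                   Gf0 = 0.04, kf = 0.1, Gb0 = 0.02, kb = 0.15, q = 1,
                   Gd1 = 0.1, Gd2 = 0.01, Gr0 = 0.00033,
                   E = 0, v0 = 43)
    if (model_order == 6) common <- c(common, list(Go1 = 2, Go2 = 2))
    opsin_params(model_order, common)
  }
}

#' Serialize / deserialize parameter records
#'
#' Parameter sets round-trip to JSON or YAML as a flat name-to-value map
#' plus \code{model_order}. JSON numbers are written at full precision so
#' decimal literals survive a round-trip exactly.
#'
#' @param p An \code{opsin_params} object.
#' @param path Output (or input) file path; format chosen by extension
#'   (\code{.json}, \code{.yaml}/\code{.yml}).
#' @return \code{write_params} returns \code{path} invisibly;
#'   \code{read_params} returns an \code{opsin_params} object.
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "opsin_params"))
  flat <- c(list(model_order = p$model_order,
                 constrain_v1 = isTRUE(p$constrain_v1)),
            p[.param_fields(p$model_order)])
  if (grepl("\\.(yaml|yml)$", path)) {
    yaml::write_yaml(flat, path, precision = 15)
  } else {
    writeLines(jsonlite::toJSON(flat, auto_unbox = TRUE, digits = NA), path)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  flat <- if (grepl("\\.(yaml|yml)$", path)) yaml::read_yaml(path)
          else jsonlite::fromJSON(readLines(path, warn = FALSE))
  order <- flat$model_order
  cv1 <- if (is.null(flat$constrain_v1)) TRUE else isTRUE(flat$constrain_v1)
  flat$model_order <- NULL
  flat$constrain_v1 <- NULL
  opsin_params(order, flat, constrain_v1 = cv1)
}
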