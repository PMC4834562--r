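.fmt <- function(x) sprintf("%.12g", x)

.csv_num <- function(x) sprintf("%.17g", x)

#' Write / read a photocurrent trace as CSV
#'
#' Columns: \code{t_ms}, \code{I_nA}, \code{phi} (instantaneous flux,
#' reconstructed from the pulse windows and the nominal flux), plus one
#' column per photocycle state when a trajectory is stored. Numbers are
#' written with 17 significant digits so a round-trip reproduces the
#' doubles exactly. Pulse/voltage annotations travel in the protocol
#' manifest, not the CSV (see [write_protocol_data()]).
#'
#' @param pc A [photocurrent()].
#' @param path CSV output path.
#' @return \code{path}, invisibly.
#' @export
write_photocurrent_csv <- function(pc, path) {
  stopifnot(inherits(pc, "photocurrent"))
  phi_t <- rep(0, length(pc$t))
  for (k in seq_len(nrow(pc$pulses)))
    phi_t[pc$t >= pc$pulses[k, 1] - 1e-12 &
          pc$t < pc$pulses[k, 2] - 1e-12] <- pc$phi
  df <- data.frame(t_ms = .csv_num(pc$t), I_nA = .csv_num(pc$I),
                   phi = .csv_num(phi_t), check.names = FALSE)
  if (!is.null(pc$states))
    for (s in colnames(pc$states)) df[[s]] <- .csv_num(pc$states[, s])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_photocurrent_csv
#' @param pulses,phi,V Annotations (normally supplied by the manifest).
#' @export
read_photocurrent_csv <- function(path, pulses, phi, V = NA_real_) {
  df <- utils::read.csv(path, check.names = FALSE)
  state_cols <- setdiff(names(df), c("t_ms", "I_nA", "phi"))
  states <- if (length(state_cols)) as.matrix(df[state_cols]) else NULL
  photocurrent(I = df$I_nA, t = df$t_ms, pulses = pulses, phi = phi, V = V,
               states = states)
}

#' Export / import a protocol data set as CSVs plus a JSON manifest
#'
#' Each trial becomes one CSV; \code{manifest.json} records the protocol
#' name, grid and per-trial annotations (file, run, phi, V, pulses) so the
#' set can be reconstructed exactly.
#'
#' @param pd A [protocol_data()] set.
#' @param dir Output directory (created if needed).
#' @return \code{dir} (or, for the reader, a \code{protocol_data}),
#'   invisibly.
#' @export
write_protocol_data <- function(pd, dir) {
  stopifnot(inherits(pd, "protocol_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  trials <- vector("list", length(pd$trials))
  for (i in seq_along(pd$trials)) {
    pc <- pd$trials[[i]]
    file <- sprintf("trial_%03d.csv", i)
    write_photocurrent_csv(pc, file.path(dir, file))
    trials[[i]] <- list(file = file, run = pd$index$run[i],
                        phi = pc$phi, V = pc$V,
                        pulses = lapply(seq_len(nrow(pc$pulses)),
                                        function(k) pc$pulses[k, ]))
  }
  manifest <- list(protocol = pd$protocol, n_runs = pd$n_runs,
                   phis = pd$phis, Vs = pd$Vs, trials = trials)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' @rdname write_protocol_data
#' @export
read_protocol_data <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                                 simplifyDataFrame = FALSE)
  pd <- protocol_data(manifest$protocol, n_runs = manifest$n_runs,
                      phis = unlist(manifest$phis), Vs = unlist(manifest$Vs))
  for (tr in manifest$trials) {
    pulses <- do.call(rbind, lapply(tr$pulses, unlist))
    pc <- read_photocurrent_csv(file.path(dir, tr$file), pulses = pulses,
                                phi = tr$phi, V = tr$V)
    pd <- add_trial(pd, pc, run = tr$run)
  }
  pd
}

.nmodl_units <- c(
  g0 = "(pS)", gamma = "(1)", phi_m = "(photons/mm2/s)",
  k1 = "(/ms)", k2 = "(/ms)", ka = "(/ms)", kr = "(/ms)", p = "(1)",
  q = "(1)", kf = "(/ms)", kb = "(/ms)", Gf0 = "(/ms)", Gb0 = "(/ms)",
  Go1 = "(/ms)", Go2 = "(/ms)", Gd = "(/ms)", Gd1 = "(/ms)",
  Gd2 = "(/ms)", Gr0 = "(/ms)", E = "(mV)", v0 = "(mV)", v1 = "(mV)")

.nmodl_derivs <- function(order) {
  switch(as.character(order),
    "3" = c("C' = Gr * D - Ga * C",
            "O' = Ga * C - Gd * O",
            "D' = Gd * O - Gr * D"),
    "4" = c("C1' = Gd1 * O1 + Gr0 * C2 - Ga1 * C1",
            "O1' = Ga1 * C1 + Gb * O2 - (Gd1 + Gf) * O1",
            "O2' = Ga2 * C2 + Gf * O1 - (Gd2 + Gb) * O2",
            "C2' = Gd2 * O2 - (Gr0 + Ga2) * C2"),
    "6" = c("C1' = Gd1 * O1 + Gr0 * C2 - Ga1 * C1",
            "I1' = Ga1 * C1 - Go1 * I1",
            "O1' = Go1 * I1 + Gb * O2 - (Gd1 + Gf) * O1",
            "O2' = Go2 * I2 + Gf * O1 - (Gd2 + Gb) * O2",
            "I2' = Ga2 * C2 - Go2 * I2",
            "C2' = Gd2 * O2 - (Gr0 + Ga2) * C2"))
}

.rate_lines <- function(order) {
  if (order == 3)
    c("Ga = ka * hill(phi, p)",
      "Gr = kr * hill(phi, q) + Gr0")
  else
    c("Ga1 = k1 * hill(phi, p)",
      "Ga2 = k2 * hill(phi, p)",
      "Gf = kf * hill(phi, q) + Gf0",
      "Gb = kb * hill(phi, q) + Gb0")
}

#' Emit an NMODL mechanism for a compartmental simulator
#'
#' Generates a NEURON-dialect NMODL file transcribing the model's kinetic
#' scheme: a STATE block naming exactly the photocycle states, a PARAMETER
#' block carrying every parameter with units and its current value, and a
#' DERIVATIVE block with the state equations. Output is byte-identical for
#' identical input.
#'
#' @param params An [opsin_params()] record.
#' @return A single string (the .mod file contents).
#' @export
emit_nmodl <- function(params) {
  stopifnot(inherits(params, "opsin_params"))
  n <- params$model_order
  sts <- state_names(n)
  fields <- .param_fields(n)
  par_lines <- sprintf("    %s = %s %s", fields,
                       .fmt(vapply(fields, function(f) params[[f]],
                                   numeric(1))),
                       .nmodl_units[fields])
  rate_names <- if (n == 3) c("Ga", "Gr") else c("Ga1", "Ga2", "Gf", "Gb")
  txt <- c(
    sprintf("TITLE %d-state opsin photocycle mechanism", n),
    "",
    "NEURON {",
    sprintf("    SUFFIX RhO%d", n),
    "    NONSPECIFIC_CURRENT i",
    sprintf("    RANGE i, phi, g0, gamma, E, v0, v1"),
    "}",
    "",
    "UNITS {",
    "    (nA) = (nanoamp)",
    "    (mV) = (millivolt)",
    "    (pS) = (picosiemens)",
    "}",
    "",
    "PARAMETER {",
    "    phi = 0 (photons/mm2/s)",
    par_lines,
    "}",
    "",
    "ASSIGNED {",
    "    v (mV)",
    "    i (nA)",
    sprintf("    %s (/ms)", rate_names),
    "    fphi (1)",
    "    fv (1)",
    "}",
    "",
    sprintf("STATE { %s }", paste(sts, collapse = " ")),
    "",
    "BREAKPOINT {",
    "    SOLVE kin METHOD sparse",
    if (n == 3) "    fphi = O" else "    fphi = O1 + gamma * O2",
    "    fv = rectifier(v)",
    "    i = g0 * fphi * fv * (v - E) * 1e-6",
    "}",
    "",
    "INITIAL {",
    sprintf("    %s = %d", sts, c(1L, rep(0L, length(sts) - 1))),
    "    setrates(phi)",
    "}",
    "",
    "KINETIC kin {",
    "    setrates(phi)",
    "}",
    "",
    "DERIVATIVE states {",
    paste0("    ", .nmodl_derivs(n)),
    "}",
    "",
    "FUNCTION hill(f (photons/mm2/s), e (1)) (1) {",
    "    hill = (f / phi_m)^e / ((f / phi_m)^e + 1)",
    "}",
    "",
    "FUNCTION rectifier(vm (mV)) (1) {",
    "    rectifier = (v1 / (vm - E)) * (1 - exp(-(vm - E) / v0))",
    "}",
    "",
    "PROCEDURE setrates(f (photons/mm2/s)) {",
    paste0("    ", .rate_lines(n)),
    "}")
  paste(txt, collapse = "\n")
}

#' Emit model-description equation text for a network simulator
#'
#' Produces the kinetic scheme as plain differential-equation strings in
#' the style used by equation-oriented spiking-network simulators, with
#' parameter values substituted from the record. Byte-identical output for
#' identical input.
#'
#' @param params An [opsin_params()] record.
#' @return A single string.
#' @export
emit_network_equations <- function(params) {
  stopifnot(inherits(params, "opsin_params"))
  n <- params$model_order
  fields <- .param_fields(n)
  hdr <- sprintf("# %d-state opsin photocycle equations", n)
  par_lines <- sprintf("%s = %s", fields,
                       .fmt(vapply(fields, function(f) params[[f]],
                                   numeric(1))))
  deriv <- gsub("^([A-Za-z0-9]+)' = (.*)$", "d\\1/dt = (\\2) / ms : 1",
                .nmodl_derivs(n))
  rates <- paste0(.rate_lines(n), " : rate (/ms)")
  hill <- "hill(x, e) = (x / phi_m)^e / ((x / phi_m)^e + 1)"
  fphi <- if (n == 3) "fphi = O : 1" else "fphi = O1 + gamma * O2 : 1"
  eqs <- c(hdr, "", "# parameters", par_lines, "",
           "# light-dependent rates", hill, rates, "",
           "# state equations", deriv, "",
           "# conductance",
           fphi,
           "fv = (v1 / (v - E)) * (1 - exp(-(v - E) / v0)) : 1",
           "I_opsin = g0 * fphi * fv * (v - E) * 1e-6 : amp")
  paste(eqs, collapse = "\n")
}
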