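#' Cell roles of the DG-CA3 micro-network
#'
#' The network holds one cell per role: granule cell (`G`), DG GABAergic
#' interneuron (`DI`), mossy cell soma and dendrite (`MS`/`MD`, one
#' two-compartment cell), CA3 pyramidal cell (`P`), CA3 GABAergic
#' interneuron (`I`) and O-LM cell (`O`).
#'
#' @return Character vector of the seven recorded compartment labels.
#' @export
cell_kinds <- function() c("G", "DI", "MS", "MD", "P", "I", "O")

#' Default biophysical parameters for one cell role
#'
#' Granule, pyramidal and O-LM cells are single-compartment Hodgkin-Huxley
#' models: granule cell with Traub-Miles sodium/potassium kinetics; the
#' pyramidal cell is a reduced CA1-type model (instantaneous Na activation,
#' persistent Na, A-current and a slow M-like K current) capable of tonic
#' spiking, burst discharges and depolarisation block, and
#' the O-LM cell an h-current plus a strong M-type adaptation current that
#' keeps its firing in the slow (5-12 Hz) range typical of O-LM cells.  Both GABAergic interneurons use the
#' Wang-Buzsaki fast-spiking template.  The mossy cell is a two-compartment
#' Pinsky-Rinzel model (soma: Na, K-DR; dendrite: Ca, K-C, K-AHP) with its
#' native rate functions shifted so that rest sits near -60 mV.
#'
#' Units: conductances mS/cm2, potentials mV, capacitance uF/cm2, applied
#' current uA/cm2.  Calcium is in the dimensionless units of the
#' Pinsky-Rinzel model.
#'
#' @param kind One of `"G"`, `"DI"`, `"P"`, `"I"`, `"O"`, `"mossy"`.
#' @param i_ext Constant applied current; the network default applies the
#'   same value to every cell (for the mossy cell it enters the soma).
#' @return Named list of parameters with class `"dgca3_cell_params"`.
#' @export
cell_params <- function(kind, i_ext = NULL) {
  p <- switch(kind,
    G = list(Cm = 1, gNa = 100, gK = 80, gL = 0.1, ENa = 50, EK = -100,
             EL = -67, Iext = 0.35),
    DI = list(Cm = 1, gNa = 35, gK = 9, gL = 0.1, ENa = 55, EK = -90,
              EL = -65, Iext = 0.35, phi = 5),
    P = list(Cm = 1, gNa = 35, gK = 9, gL = 0.05, ENa = 55, EK = -90,
             EL = -70, Iext = 1.225, gM = 1, gNaP = 0.08, gA = 1.6),
    I = list(Cm = 1, gNa = 35, gK = 9, gL = 0.1, ENa = 55, EK = -90,
             EL = -65, Iext = 0.35, phi = 5),
    O = list(Cm = 1, gNa = 100, gK = 80, gL = 0.15, ENa = 50, EK = -100,
             EL = -67, Iext = 0.35, gh = 0.1, Eh = -32.9, gM = 0.7),
    mossy = list(Cm = 3, gNa = 30, gKdr = 15, gCa = 7, gKC = 15,
                 gKahp = 0.4, gLs = 0.15, gLd = 0.15, gc = 2.1, p = 0.5,
                 ENa = 60, EK = -75, ECa = 80, EL = -65, Is = 1.05, Id = 0),
    stop("unknown cell kind '", kind, "'")
  )
  if (!is.null(i_ext)) {
    if (kind == "mossy") p$Is <- i_ext else p$Iext <- i_ext
  }
  structure(p, kind = kind, class = "dgca3_cell_params")
}

# fixed parameter order expected by the compiled right-hand sides
.param_order <- function(kind) {
  switch(kind,
    G = c("Cm", "gNa", "gK", "gL", "ENa", "EK", "EL", "Iext"),
    P = c("Cm", "gNa", "gK", "gL", "ENa", "EK", "EL", "Iext", "gM", "gNaP",
          "gA"),
    O = c("Cm", "gNa", "gK", "gL", "ENa", "EK", "EL", "Iext", "gh", "Eh",
          "gM"),
    DI = ,
    I = c("Cm", "gNa", "gK", "gL", "ENa", "EK", "EL", "Iext", "phi"),
    mossy = c("Cm", "gNa", "gKdr", "gCa", "gKC", "gKahp", "gLs", "gLd",
              "gc", "p", "ENa", "EK", "ECa", "EL", "Is", "Id"),
    stop("unknown cell kind '", kind, "'")
  )
}

.param_vec <- function(params) {
  kind <- attr(params, "kind")
  ord <- .param_order(kind)
  miss <- setdiff(ord, names(params))
  if (length(miss))
    stop("missing parameters for ", kind, ": ", paste(miss, collapse = ", "))
  unlist(params[ord])
}

.state_names <- function(kind) {
  switch(kind,
    G = c("V", "m", "h", "n"),
    P = c("V", "h", "n", "b", "z"),
    O = c("V", "m", "h", "n", "r", "w"),
    DI = ,
    I = c("V", "h", "n"),
    mossy = c("Vs", "Vd", "h", "n", "s", "c", "q", "Ca"),
    stop("unknown cell kind '", kind, "'")
  )
}

#' Opening and closing rates of a gating variable
#'
#' Returns the voltage-dependent transition rates `alpha` and `beta`
#' (1/ms) of a Hodgkin-Huxley-style gate, with removable singularities of
#' the rate expressions evaluated by their analytic limits.  For gates
#' governed by steady-state/time-constant kinetics (the pyramidal M-current
#' gate `w`, the O-LM h-current gate `r`) the equivalent rates
#' `alpha = x_inf/tau`, `beta = (1 - x_inf)/tau` are returned.  For the
#' calcium-dependent mossy AHP gate `q` the argument `v` is read as the
#' calcium concentration.
#'
#' @param kind Cell kind (see [cell_kinds()]; `"MS"`/`"MD"` address the
#'   mossy soma/dendrite gates).
#' @param gate Gate name, e.g. `"m"`, `"h"`, `"n"`, `"s"`, `"c"`, `"q"`,
#'   `"w"`, `"r"`.
#' @param v Membrane potential (mV), vectorised.
#' @return Data frame with columns `alpha` and `beta` (1/ms).
#' @export
gate_rates <- function(kind, gate, v) {
  stopifnot(is.finite(v))
  out <- vapply(v, function(vi) gate_rates_cpp(kind, gate, vi), numeric(2))
  data.frame(alpha = out[1, ], beta = out[2, ])
}

#' Time derivative of a single-compartment HH-type cell
#'
#' @param state Named numeric vector, `c(V, gates...)` in the order of the
#'   cell kind's state layout (`V,m,h,n` plus `w` for `P`, `r` for `O`;
#'   `V,h,n` for the interneurons).
#' @param params A [cell_params()] object for a single-compartment kind.
#' @param i_syn Total synaptic current (uA/cm2, positive outward).
#' @return Named vector of time derivatives (mV/ms, 1/ms).
#' @export
hh_rhs <- function(state, params, i_syn = 0) {
  kind <- attr(params, "kind")
  if (kind == "mossy") stop("use pr_rhs() for the two-compartment mossy cell")
  sn <- .state_names(kind)
  stopifnot(length(state) == length(sn))
  out <- cell_rhs_cpp(kind, as.numeric(state), .param_vec(params), i_syn)
  names(out) <- sn
  out
}

#' Time derivative of the two-compartment Pinsky-Rinzel mossy cell
#'
#' Soma and dendrite are coupled by the conductance `gc`, scaled by the
#' somatic area fraction `p`; the dendritic calcium pool is driven by the
#' calcium current with linear decay.
#'
#' @param state Named numeric vector `c(Vs, Vd, h, n, s, c, q, Ca)`.
#' @param params A [cell_params()] object of kind `"mossy"`.
#' @param i_syn_soma,i_syn_dend Synaptic currents into each compartment
#'   (uA/cm2 of total membrane, positive outward).
#' @return Named vector of time derivatives.
#' @export
pr_rhs <- function(state, params, i_syn_soma = 0, i_syn_dend = 0) {
  stopifnot(attr(params, "kind") == "mossy", length(state) == 8)
  out <- cell_rhs_cpp("mossy", as.numeric(state), .param_vec(params),
                      i_syn_soma, i_syn_dend)
  names(out) <- .state_names("mossy")
  out
}

#' Resting initial state of one cell
#'
#' Voltage starts at the leak reversal and every gate at its steady state
#' for that voltage; dendritic calcium starts at a small positive value.
#'
#' @param params A [cell_params()] object.
#' @return Named state vector.
#' @export
rest_state <- function(params) {
  kind <- attr(params, "kind")
  g_inf <- function(k, gate, v) {
    r <- gate_rates_cpp(k, gate, v)
    r[["alpha"]] / (r[["alpha"]] + r[["beta"]])
  }
  if (kind == "mossy") {
    v0 <- params$EL
    st <- c(Vs = v0, Vd = v0, h = g_inf("MS", "h", v0), n = g_inf("MS", "n", v0),
            s = g_inf("MD", "s", v0), c = g_inf("MD", "c", v0),
            q = 0, Ca = 0.2)
    st[["q"]] <- g_inf("MS", "q", 0.2)
    return(st)
  }
  v0 <- params$EL
  sn <- .state_names(kind)
  st <- stats::setNames(numeric(length(sn)), sn)
  st[["V"]] <- v0
  for (g in setdiff(sn, "V")) st[[g]] <- g_inf(kind, g, v0)
  st
}
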