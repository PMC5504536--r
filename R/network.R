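#' Build a DG-CA3 network configuration
#'
#' One configuration object is the single source of truth for a scenario:
#' backprojection mode, every synaptic conductance, external drive, cell
#' parameter overrides and integration settings.
#'
#' The three conductances that the experiments sweep (`g_nmda_p`: mossy to
#' pyramidal NMDA; `g_p_ms`: pyramidal to mossy-soma backprojection;
#' `g_p_di`: pyramidal to DG-interneuron backprojection) are given on the
#' relative scale used throughout the experiment descriptions (values of
#' order 1e-4..1e-1).  `syn_gain` converts that relative scale to absolute
#' conductance density (mS/cm2) and multiplies every synaptic conductance;
#' its default is part of the shipped calibration.
#'
#' @param backprojection `"mossy_soma"` (pyramidal drives the mossy soma)
#'   or `"dg_interneuron"` (pyramidal drives the DG interneuron).
#' @param g_nmda_p Mossy-to-pyramidal NMDA conductance (relative scale).
#' @param g_p_ms Backprojection conductance in `"mossy_soma"` mode; must be
#'   0 in the other mode.
#' @param g_p_di Backprojection conductance in `"dg_interneuron"` mode;
#'   must be 0 in the other mode.
#' @param g_c Soma-dendrite coupling conductance of the mossy cell
#'   (mS/cm2).
#' @param conductances Named list overriding the remaining intra-network
#'   edge conductances (relative scale): `g_g_ms`, `g_g_di`, `g_di_g`,
#'   `g_di_ms`, `g_ms_g`, `g_ms_di`, `g_ampa_p`, `g_p_i`, `g_p_o`,
#'   `g_i_p`, `g_o_p`.
#' @param include_io Include mutual CA3 interneuron/O-LM inhibition
#'   (`g_i_o`, `g_o_i`); off by default.
#' @param i_ext Constant external current applied identically to every
#'   cell (uA/cm2; enters the mossy soma).
#' @param i_ext_cells Optional named per-cell overrides of `i_ext`, e.g.
#'   `list(P = 0.2)`; names among `G, DI, mossy, P, I, O`.
#' @param cell_overrides Named list of parameter overrides per cell, e.g.
#'   `list(P = list(gM = 1.2))`.
#' @param syn_gain Global synaptic gain converting relative conductances
#'   to mS/cm2.
#' @param duration_s Simulated time (s).
#' @param step_ms Integration step (ms) of the fixed-step RK4 solver.
#' @param record_dt_ms Sampling interval of recorded traces (ms); must be
#'   a multiple of `step_ms`.
#' @param v_thresh Spike detection threshold (mV).
#' @param mg Extracellular magnesium (mM) for all NMDA synapses.
#' @return Object of class `"dgca3_config"`.
#' @export
network_config <- function(backprojection = c("mossy_soma", "dg_interneuron"),
                           g_nmda_p = 0.001,
                           g_p_ms = NULL, g_p_di = NULL,
                           g_c = 2.1,
                           conductances = list(),
                           include_io = FALSE,
                           i_ext = 0.35, i_ext_cells = list(),
                           cell_overrides = list(),
                           syn_gain = 200,
                           duration_s = 10, step_ms = 0.01,
                           record_dt_ms = 0.05,
                           v_thresh = -20, mg = 1) {
  backprojection <- match.arg(backprojection)
  if (is.null(g_p_ms)) g_p_ms <- if (backprojection == "mossy_soma") 1e-4 else 0
  if (is.null(g_p_di)) g_p_di <- if (backprojection == "dg_interneuron") 0.001 else 0
  g <- .default_conductances()
  unknown <- setdiff(names(conductances), names(g))
  if (length(unknown))
    stop("unknown conductance name(s): ", paste(unknown, collapse = ", "))
  g[names(conductances)] <- conductances
  cfg <- list(backprojection = backprojection, g_nmda_p = g_nmda_p,
              g_p_ms = g_p_ms, g_p_di = g_p_di, g_c = g_c,
              conductances = g, include_io = include_io,
              i_ext = i_ext, i_ext_cells = i_ext_cells,
              cell_overrides = cell_overrides, syn_gain = syn_gain,
              duration_s = duration_s, step_ms = step_ms,
              record_dt_ms = record_dt_ms, v_thresh = v_thresh, mg = mg)
  structure(cfg, class = "dgca3_config")
}

# intra-network couplings not swept by any experiment; part of the shipped
# calibration (relative scale, multiplied by syn_gain)
.default_conductances <- function() {
  list(g_g_ms = 1e-3,   # granule -> mossy dendrite, AMPA (mossy fiber)
       g_g_di = 5e-4,    # granule -> DG interneuron, AMPA
       g_di_g = 5e-4,    # DG interneuron -> granule, GABA_A
       g_di_ms = 1e-3,   # DG interneuron -> mossy soma, GABA_A
       g_ms_g = 2e-4,    # mossy -> granule, NMDA
       g_ms_di = 2e-4,   # mossy -> DG interneuron, AMPA
       g_ampa_p = 5e-4,  # mossy -> pyramidal, AMPA (with the NMDA edge)
       g_p_i = 5e-4,     # pyramidal -> CA3 interneuron, AMPA
       g_p_o = 4e-3,     # pyramidal -> O-LM, AMPA
       g_i_p = 1e-3,     # CA3 interneuron -> pyramidal, GABA_A
       g_o_p = 1e-3,     # O-LM -> pyramidal, GABA_A
       g_i_o = 5e-4, g_o_i = 5e-4)
}

#' Validate a network configuration
#'
#' @param config A [network_config()] object.
#' @return Character vector of violations, each naming the offending
#'   field; empty when the configuration is valid.
#' @export
validate_config <- function(config) {
  v <- character()
  chk <- function(cond, msg) if (isTRUE(cond)) v else c(v, msg)
  if (!inherits(config, "dgca3_config")) return("config: not a dgca3_config")
  for (f in c("g_nmda_p", "g_p_ms", "g_p_di", "g_c", "syn_gain"))
    v <- chk(config[[f]] >= 0, paste0(f, ": must be >= 0"))
  for (nm in names(config$conductances))
    v <- chk(config$conductances[[nm]] >= 0, paste0(nm, ": must be >= 0"))
  if (config$backprojection == "mossy_soma")
    v <- chk(config$g_p_di == 0,
             "g_p_di: must be 0 in mossy_soma backprojection mode")
  else
    v <- chk(config$g_p_ms == 0,
             "g_p_ms: must be 0 in dg_interneuron backprojection mode")
  v <- chk(config$duration_s > 0, "duration_s: must be > 0")
  v <- chk(config$step_ms > 0, "step_ms: must be > 0")
  v <- chk(config$record_dt_ms >= config$step_ms,
           "record_dt_ms: must be >= step_ms")
  if (config$step_ms > 0)
    v <- chk(abs(config$record_dt_ms / config$step_ms -
                 round(config$record_dt_ms / config$step_ms)) < 1e-8,
             "record_dt_ms: must be a multiple of step_ms")
  v <- chk(config$mg >= 0, "mg: must be >= 0")
  v
}

#' Build the network connection list
#'
#' Expands a configuration into the fixed edge set of the DG-CA3 wiring:
#' within DG, the granule cell excites mossy dendrite and DG interneuron
#' (AMPA), the DG interneuron inhibits granule and mossy soma (GABA_A),
#' and the mossy cell excites the granule cell via NMDA and the DG
#' interneuron via AMPA; the mossy cell drives the pyramidal cell through
#' paired NMDA + AMPA mossy-fiber edges; within CA3 the pyramidal cell
#' excites both interneuron and O-LM (AMPA) and receives GABA_A inhibition
#' from both; the backprojection is a single AMPA-type edge, either
#' pyramidal-to-mossy-soma or pyramidal-to-DG-interneuron depending on the
#' configured mode.
#'
#' @param config A valid [network_config()].
#' @return Data frame of synapse specifications with one row per edge:
#'   `pre`, `post`, `compartment`, `receptor`, `g_rel` (relative scale),
#'   `g_max` (effective, mS/cm2, `= g_rel * syn_gain`), `E_rev`, `alpha`,
#'   `beta`, `mg`.
#' @export
build_network <- function(config) {
  viol <- validate_config(config)
  if (length(viol)) stop("invalid config: ", paste(viol, collapse = "; "))
  g <- config$conductances
  e <- function(pre, post, receptor, g_rel, compartment = "soma") {
    kin <- receptor_kinetics(receptor)
    data.frame(pre = pre, post = post, compartment = compartment,
               receptor = receptor, g_rel = g_rel,
               g_max = g_rel * config$syn_gain, E_rev = kin$E_rev,
               alpha = kin$alpha, beta = kin$beta,
               mg = if (receptor == "NMDA") config$mg else 0)
  }
  edges <- rbind(
    e("G", "mossy", "AMPA", g$g_g_ms, "dendrite"),
    e("G", "DI", "AMPA", g$g_g_di),
    e("DI", "G", "GABA_A", g$g_di_g),
    e("DI", "mossy", "GABA_A", g$g_di_ms),
    e("MS", "G", "NMDA", g$g_ms_g),
    e("MS", "DI", "AMPA", g$g_ms_di),
    e("MS", "P", "NMDA", config$g_nmda_p),
    e("MS", "P", "AMPA", g$g_ampa_p),
    e("P", "I", "AMPA", g$g_p_i),
    e("P", "O", "AMPA", g$g_p_o),
    e("I", "P", "GABA_A", g$g_i_p),
    e("O", "P", "GABA_A", g$g_o_p)
  )
  if (config$include_io)
    edges <- rbind(edges, e("I", "O", "GABA_A", g$g_i_o),
                   e("O", "I", "GABA_A", g$g_o_i))
  edges <- rbind(edges, if (config$backprojection == "mossy_soma")
    e("P", "mossy", "AMPA", config$g_p_ms, "soma")
  else
    e("P", "DI", "AMPA", config$g_p_di))
  key <- with(edges, paste(pre, post, receptor, compartment))
  stopifnot(!anyDuplicated(key))
  rownames(edges) <- NULL
  edges
}

# numeric edge matrix for the compiled integrator
.edge_matrix <- function(edges) {
  pre_col <- c(G = 0, DI = 1, MS = 2, MD = 3, P = 4, I = 5, O = 6)
  post_cell <- c(G = 0, DI = 1, mossy = 2, P = 3, I = 4, O = 5)
  rec <- c(AMPA = 0, NMDA = 1, GABA_A = 2)
  m <- cbind(pre_col[edges$pre], post_cell[edges$post],
             ifelse(edges$compartment == "dendrite", 1, 0),
             rec[edges$receptor], edges$g_max, edges$E_rev,
             edges$alpha, edges$beta, edges$mg)
  dimnames(m) <- NULL
  m
}

# assembled cell parameter lists for a config, in integrator order
.config_cells <- function(config) {
  roster <- c("G", "DI", "mossy", "P", "I", "O")
  lapply(roster, function(k) {
    # the common external stimulus is scaled per cell kind so that the
    # injected drive sits comparably relative to each model's rheobase
    # (the mossy cell has 3x the capacitance, the pyramidal model a much
    # smaller leak); the factors are part of the shipped calibration
    scale <- c(G = 1, DI = 1, mossy = 3, P = 3.5, I = 1, O = 1)[[k]]
    p <- cell_params(k, i_ext = config$i_ext_cells[[k]] %||% (config$i_ext * scale))
    if (k == "mossy") p$gc <- config$g_c
    ov <- config$cell_overrides[[k]]
    if (!is.null(ov)) p[names(ov)] <- ov
    structure(p, kind = k, class = "dgca3_cell_params")
  })
}
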