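#' Receptor kinds and their default kinetics
#'
#' Synaptic transmission uses the first-order kinetic scheme
#' `ds/dt = alpha * T(V_pre) * (1 - s) - beta * s`, where `T` is the
#' sigmoidal presynaptic transmitter drive.  Default time constants:
#' AMPA decays in ~2 ms, GABA_A in ~7 ms, NMDA rises in ~2 ms and decays
#' in ~100 ms.  Reversal potentials default to 0 mV (AMPA/NMDA) and
#' -75 mV (GABA_A); the NMDA conductance is additionally scaled by the
#' voltage-dependent magnesium block [mg_block()].
#'
#' @param receptor `"AMPA"`, `"NMDA"` or `"GABA_A"`.
#' @return Named list with `alpha`, `beta` (1/ms), `E_rev` (mV) and, for
#'   NMDA, `mg` (mM).
#' @export
receptor_kinetics <- function(receptor) {
  switch(receptor,
    AMPA = list(alpha = 1.1, beta = 0.5, E_rev = 0, mg = 0),
    NMDA = list(alpha = 0.49, beta = 0.01, E_rev = 0, mg = 1),
    GABA_A = list(alpha = 1.0, beta = 1 / 7, E_rev = -75, mg = 0),
    stop("unknown receptor kind '", receptor, "'")
  )
}

#' Presynaptic transmitter drive
#'
#' Sigmoid of the presynaptic membrane potential, 0.5 at +2 mV with a
#' 5-mV slope: effectively 0 at rest and saturating to 1 at the spike
#' peak, so each presynaptic spike delivers a ~1-ms unit pulse of drive.
#'
#' @param v_pre Presynaptic potential (mV), vectorised.
#' @return Drive in (0, 1).
#' @export
transmitter_drive <- function(v_pre) {
  stopifnot(all(is.finite(v_pre)))
  vapply(v_pre, drive_cpp, numeric(1))
}

#' Voltage-dependent NMDA magnesium block
#'
#' Standard closed form `B(V) = 1 / (1 + exp(-0.062 V) [Mg]/3.57)` with
#' `[Mg]` in mM.
#'
#' @param v Postsynaptic potential (mV), vectorised.
#' @param mg Extracellular magnesium concentration (mM), default 1.
#' @return Block factor in (0, 1]; 1 when `mg = 0`.
#' @export
mg_block <- function(v, mg = 1) {
  if (mg < 0) stop("negative Mg concentration")
  vapply(v, mg_block_cpp, numeric(1), mg = mg)
}

#' Construct one synaptic connection
#'
#' @param pre,post Cell kinds of the pre- and postsynaptic cell (presynaptic
#'   mossy output is read from the soma `MS`).
#' @param receptor Receptor kind.
#' @param g_max Maximal conductance (mS/cm2), before any global synaptic
#'   gain is applied.
#' @param target_compartment `"soma"` (also used for whole single-compartment
#'   cells) or `"dendrite"` (mossy cell only).
#' @param alpha,beta,E_rev,mg Kinetic overrides; defaults from
#'   [receptor_kinetics()].
#' @return Named list with class `"dgca3_synapse_spec"`.
#' @export
synapse_spec <- function(pre, post, receptor, g_max,
                         target_compartment = "soma",
                         alpha = NULL, beta = NULL, E_rev = NULL, mg = NULL) {
  kin <- receptor_kinetics(receptor)
  spec <- list(pre = pre, post = post, receptor = receptor, g_max = g_max,
               target_compartment = target_compartment,
               alpha = alpha %||% kin$alpha, beta = beta %||% kin$beta,
               E_rev = E_rev %||% kin$E_rev, mg = mg %||% kin$mg)
  stopifnot(spec$g_max >= 0, spec$alpha > 0, spec$beta > 0)
  structure(spec, class = "dgca3_synapse_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Time derivative of a synaptic gating fraction
#'
#' @param s Gating fraction in `[0, 1]`.
#' @param spec A [synapse_spec()].
#' @param v_pre Presynaptic potential (mV).
#' @return `ds/dt` (1/ms).
#' @export
synapse_rhs <- function(s, spec, v_pre) {
  stopifnot(s >= 0, s <= 1)
  spec$alpha * drive_cpp(v_pre) * (1 - s) - spec$beta * s
}

#' Postsynaptic current of one synapse
#'
#' `I = g_max * s * (V_post - E_rev)`, multiplied by the magnesium block
#' for NMDA.  Positive current is outward and is subtracted in `dV/dt`.
#'
#' @param s Gating fraction.
#' @param spec A [synapse_spec()].
#' @param v_post Postsynaptic potential (mV).
#' @return Current (uA/cm2).
#' @export
synaptic_current <- function(s, spec, v_post) {
  i <- spec$g_max * s * (v_post - spec$E_rev)
  if (spec$receptor == "NMDA") i <- i * mg_block_cpp(v_post, spec$mg)
  i
}
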