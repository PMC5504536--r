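#' Integrate the coupled DG-CA3 network
#'
#' Advances every cell and synapse with a fixed-step 4th-order Runge-Kutta
#' scheme (gating variables clamped to `[0, 1]` after each step).  All
#' cells start from rest (leak-determined voltage, gates at steady state)
#' and all synapses closed, so identical configurations yield identical
#' results.  Integration aborts with an error naming the offending time
#' and cell if any voltage leaves +/-200 mV or turns non-finite.
#'
#' @param config A valid [network_config()].
#' @param record_synapses Also record every synaptic gating trace.
#' @param init Optional full initial state vector (cells then synapses) to
#'   resume or perturb a run.
#' @return Object of class `"dgca3_sim"`: list with `time` (ms), `traces`
#'   (matrix, one column per recorded compartment `G, DI, MS, MD, P, I,
#'   O`), `spikes` (named list of spike-time vectors, threshold crossings
#'   at full step resolution with a 2-ms refractory guard), `edges`,
#'   `config`, and integrator metadata.
#' @export
simulate_network <- function(config, record_synapses = FALSE, init = NULL) {
  viol <- validate_config(config)
  if (length(viol)) stop("invalid config: ", paste(viol, collapse = "; "))
  edges <- build_network(config)
  cells <- .config_cells(config)
  pvecs <- lapply(cells, .param_vec)
  nsyn <- nrow(edges)
  if (is.null(init)) {
    init <- c(unlist(lapply(cells, rest_state), use.names = FALSE),
              numeric(nsyn))
  }
  every <- as.integer(round(config$record_dt_ms / config$step_ms))
  res <- integrate_network_cpp(pvecs, .edge_matrix(edges), init,
                               config$step_ms, config$duration_s * 1000,
                               every, record_synapses,
                               config$v_thresh, 2.0)
  if (!res$ok) {
    lab <- cell_kinds()[res$err_cell + 1]
    stop(sprintf("numerical blow-up at t = %.3f ms in cell %s", res$err_time, lab))
  }
  colnames(res$traces) <- cell_kinds()
  names(res$spikes) <- cell_kinds()
  out <- list(time = res$time, traces = res$traces, spikes = res$spikes,
              edges = edges, config = config,
              final_state = res$final_state,
              method = "rk4", step_ms = config$step_ms,
              record_dt_ms = config$record_dt_ms)
  if (record_synapses) {
    colnames(res$syn) <- paste(edges$pre, edges$post, edges$receptor, sep = ".")
    out$syn <- res$syn
  }
  structure(out, class = "dgca3_sim")
}

#' @export
print.dgca3_sim <- function(x, ...) {
  cat("DG-CA3 network simulation\n")
  cat(sprintf("  duration: %.3f s, step %.3g ms (RK4), sampled at %.3g ms\n",
              max(x$time) / 1000, x$step_ms, x$record_dt_ms))
  cat(sprintf("  backprojection: %s, g_NMDA-P = %g\n",
              x$config$backprojection, x$config$g_nmda_p))
  n <- vapply(x$spikes, length, integer(1))
  cat("  spikes:", paste(sprintf("%s=%d", names(n), n), collapse = " "), "\n")
  invisible(x)
}

#' Detect spikes in a voltage trace
#'
#' One spike per upward threshold crossing; crossings closer together
#' than the refractory guard are merged into the first.
#'
#' @param v Voltage trace (mV).
#' @param time Sample times (ms), same length as `v` (uniform grid).
#' @param threshold Crossing threshold (mV).
#' @param refractory Minimum separation between spikes (ms).
#' @return Numeric vector of spike times (ms), possibly empty.
#' @export
detect_spikes <- function(v, time, threshold = -20, refractory = 2) {
  stopifnot(length(v) == length(time), all(is.finite(v)))
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1L
  if (!length(up)) return(numeric())
  tt <- time[up]
  keep <- tt[1]
  for (t in tt[-1]) if (t - keep[length(keep)] >= refractory) keep <- c(keep, t)
  keep
}

#' Write simulation outputs as plain-text tables
#'
#' Traces go to `traces.csv` (time + one column per compartment), spike
#' trains to `spikes.csv` (cell, time_ms) and run metadata to a JSON
#' sidecar `meta.json`.
#'
#' @param sim A [simulate_network()] result.
#' @param dir Output directory (created if missing).
#' @param traces Write the (large) trace table too.
#' @return Invisibly, the paths written.
#' @export
write_sim <- function(sim, dir, traces = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  if (traces) {
    p <- file.path(dir, "traces.csv")
    utils::write.csv(data.frame(time_ms = sim$time, sim$traces),
                     p, row.names = FALSE)
    paths <- c(paths, p)
  }
  sp <- do.call(rbind, lapply(names(sim$spikes), function(k) {
    if (!length(sim$spikes[[k]])) return(NULL)
    data.frame(cell = k, time_ms = sim$spikes[[k]])
  }))
  p <- file.path(dir, "spikes.csv")
  utils::write.csv(sp %||% data.frame(cell = character(), time_ms = numeric()),
                   p, row.names = FALSE)
  paths <- c(paths, p)
  meta <- list(method = sim$method, step_ms = sim$step_ms,
               record_dt_ms = sim$record_dt_ms,
               duration_s = sim$config$duration_s,
               backprojection = sim$config$backprojection,
               g_nmda_p = sim$config$g_nmda_p,
               g_p_ms = sim$config$g_p_ms, g_p_di = sim$config$g_p_di,
               syn_gain = sim$config$syn_gain)
  p <- file.path(dir, "meta.json")
  jsonlite::write_json(meta, p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}
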