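# Shared fixtures: all simulations are generated in code, at sizes chosen
# to keep the default test run fast.

# configuration with every synaptic conductance zero: six independent cells
zero_coupling_config <- function(duration_s = 1, i_ext = 0.35, ...) {
  g0 <- as.list(stats::setNames(rep(0, 13),
                                names(dgca3net:::.default_conductances())))
  network_config(backprojection = "mossy_soma", g_nmda_p = 0, g_p_ms = 0,
                 conductances = g0, duration_s = duration_s, i_ext = i_ext,
                 ...)
}

# default mode-A network, shortened
short_config <- function(duration_s = 2, ...) {
  network_config(backprojection = "mossy_soma", duration_s = duration_s, ...)
}

firing_rate <- function(spikes, duration_s, transient_ms = 200) {
  sum(spikes > transient_ms) / (duration_s - transient_ms / 1000)
}

# synthetic voltage trace with spikes at given times (ms)
synthetic_spike_trace <- function(spike_times, duration_ms, dt = 0.1,
                                  v_rest = -65, v_peak = 30) {
  time <- seq(0, duration_ms, by = dt)
  v <- rep(v_rest, length(time))
  for (ts in spike_times) {
    idx <- which(time >= ts & time < ts + 1)   # 1-ms triangular spike
    v[idx] <- v_peak
  }
  list(time = time, v = v)
}
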