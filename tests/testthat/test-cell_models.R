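test_that("gate steady states lie in [0,1] for every gate and voltage", {
  gates <- list(G = c("m", "h", "n"), DI = c("m", "h", "n"),
                P = c("m", "h", "n", "b", "z", "p", "a"),
                I = c("m", "h", "n"), O = c("m", "h", "n", "r"),
                MS = c("m", "h", "n"), MD = c("s", "c"))
  vs <- seq(-120, 60, by = 2.5)
  for (kind in names(gates)) for (g in gates[[kind]]) {
    r <- gate_rates(kind, g, vs)
    expect_true(all(is.finite(r$alpha)), info = paste(kind, g))
    expect_true(all(is.finite(r$beta)), info = paste(kind, g))
    expect_true(all(r$alpha >= 0 & r$beta >= 0), info = paste(kind, g))
    xinf <- r$alpha / (r$alpha + r$beta)
    expect_true(all(xinf >= 0 & xinf <= 1), info = paste(kind, g))
  }
})

test_that("rates at removable singularities equal the analytic limit", {
  # granule m-gate alpha has its denominator zero at V = -54, n at V = -52
  sing <- list(c("G", "m", -54), c("G", "n", -52),
               c("DI", "m", -35), c("DI", "n", -34))
  for (s in sing) {
    at <- gate_rates(s[[1]], s[[2]], as.numeric(s[[3]]))
    lim <- gate_rates(s[[1]], s[[2]], as.numeric(s[[3]]) + c(-1e-4, 1e-4))
    expect_true(all(is.finite(unlist(at))))
    expect_equal(at$alpha, mean(lim$alpha), tolerance = 1e-6)
    expect_equal(at$beta, mean(lim$beta), tolerance = 1e-6)
  }
})

test_that("guarded rate evaluation matches the cited closed forms", {
  # direct (unguarded) evaluation of the published expressions away from
  # singular voltages is the oracle for the compiled implementation
  vs <- c(-80, -63.2, -40.7, -20, 0)
  r <- gate_rates("G", "m", vs)
  expect_equal(r$alpha, 0.32 * (vs + 54) / (1 - exp(-(vs + 54) / 4)),
               tolerance = 1e-10)
  expect_equal(r$beta, 0.28 * (vs + 27) / (exp((vs + 27) / 5) - 1),
               tolerance = 1e-10)
  r <- gate_rates("DI", "n", vs)
  expect_equal(r$alpha, 0.01 * (vs + 34) / (1 - exp(-0.1 * (vs + 34))),
               tolerance = 1e-10)
  # Pinsky-Rinzel soma n-gate on the shifted voltage u = V + 60
  u <- vs + 60
  r <- gate_rates("MS", "n", vs)
  expect_equal(r$alpha, 0.016 * (35.1 - u) / (exp((35.1 - u) / 5) - 1),
               tolerance = 1e-10)
})

test_that("hh_rhs vanishes with no currents and at the leak reversal", {
  p <- cell_params("G")
  p$gNa <- p$gK <- p$gL <- 0
  p$Iext <- 0
  st <- rest_state(p)
  d <- hh_rhs(st, p)
  expect_equal(unname(d[["V"]]), 0)

  p2 <- cell_params("G", i_ext = 0)
  p2$gNa <- p2$gK <- 0
  st2 <- rest_state(p2)          # V = EL, leak only
  expect_equal(unname(hh_rhs(st2, p2)[["V"]]), 0)
})

test_that("coarse-step spiking matches a stiff-solver oracle", {
  skip_if_not_installed("deSolve")
  p <- cell_params("G", i_ext = 2)
  y0 <- rest_state(p)
  # independent integrator: lsoda on the same right-hand side
  out <- deSolve::lsoda(y0, seq(0, 1000, by = 0.05),
                        function(t, y, parms) list(hh_rhs(y, p)),
                        rtol = 1e-8, atol = 1e-8)
  sp_oracle <- detect_spikes(out[, "V"], out[, "time"])
  cfg <- zero_coupling_config(duration_s = 1, i_ext = 2)
  sim <- simulate_network(cfg)
  sp_rk4 <- sim$spikes$G
  expect_equal(length(sp_rk4), length(sp_oracle))
  isi_o <- compute_isi(sp_oracle)
  isi_r <- compute_isi(sp_rk4)
  expect_lt(abs(median(isi_r) - median(isi_o)) / median(isi_o), 0.01)
})

test_that("mossy coupling current vanishes when compartments agree", {
  p <- cell_params("mossy")
  st <- rest_state(p)
  st[["Vs"]] <- st[["Vd"]] <- -55
  d1 <- pr_rhs(st, p)
  p2 <- p; p2$gc <- 0
  d2 <- pr_rhs(st, p2)
  expect_equal(d1, d2)   # with Vs = Vd, gc cannot matter
})

test_that("uncoupled mossy compartments evolve independently", {
  p <- cell_params("mossy")
  p$gc <- 0
  st <- rest_state(p)
  st[["Vd"]] <- -40
  base <- pr_rhs(st, p)
  st2 <- st; st2[["Vd"]] <- -80; st2[["Vs"]] <- st[["Vs"]]
  alt <- pr_rhs(st2, p)
  expect_equal(base[["Vs"]], alt[["Vs"]])   # soma blind to dendrite at gc = 0
  expect_false(isTRUE(all.equal(base[["Vd"]], alt[["Vd"]])))
})

test_that("canonical two-compartment parameters produce bursting", {
  ov <- list(mossy = list(gCa = 10, gKahp = 0.8, gLs = 0.1, gLd = 0.1,
                          EL = -60))
  cfg <- zero_coupling_config(duration_s = 4, i_ext = 0,
                              i_ext_cells = list(mossy = 0.75),
                              cell_overrides = ov)
  sim <- simulate_network(cfg)
  sp <- sim$spikes$MS[sim$spikes$MS > 500]
  isi <- compute_isi(sp)
  expect_gt(length(sp), 4)
  expect_true(any(isi < 25))            # >= 2 spikes per burst
  expect_true(any(isi > 50))            # quiescent inter-burst gaps
})

test_that("cells at rest with no drive stay at rest", {
  cfg <- zero_coupling_config(duration_s = 2, i_ext = 0)
  sim <- simulate_network(cfg)
  expect_true(all(lengths(sim$spikes) == 0))
  half <- sim$time > 1000
  for (cl in cell_kinds()) {
    v <- sim$traces[half, cl]
    expect_lt(max(v) - min(v), 1, label = paste("rest drift", cl))
  }
})

test_that("halving the step changes isolated-cell traces by < 1 mV RMS", {
  for (dt in c(0.01)) {
    c1 <- zero_coupling_config(duration_s = 1)
    c1$step_ms <- dt; c1$record_dt_ms <- 0.1
    c2 <- c1; c2$step_ms <- dt / 2
    s1 <- simulate_network(c1)
    s2 <- simulate_network(c2)
    for (cl in cell_kinds()) {
      rms <- sqrt(mean((s1$traces[, cl] - s2$traces[, cl])^2))
      expect_lt(rms, 1, label = paste("step-halving RMS", cl))
    }
  }
})

test_that("strong soma-dendrite coupling equalises the compartments", {
  base <- zero_coupling_config(duration_s = 1.5, i_ext = 0,
                               i_ext_cells = list(mossy = 0.3))
  strong <- base; strong$g_c <- 50
  s1 <- simulate_network(base)
  s2 <- simulate_network(strong)
  late <- s2$time > 1000
  gap_strong <- mean(abs(s2$traces[late, "MS"] - s2$traces[late, "MD"]))
  gap_base <- mean(abs(s1$traces[s1$time > 1000, "MS"] -
                       s1$traces[s1$time > 1000, "MD"]))
  expect_lt(gap_strong, 0.1)
  expect_lt(gap_strong, gap_base)
})

test_that("cell parameter sets round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  all_params <- sapply(c("G", "DI", "mossy", "P", "I", "O"), cell_params,
                       simplify = FALSE)
  write_cell_params(all_params, path)
  back <- read_cell_params(path)
  for (k in names(all_params))
    expect_equal(unclass(back[[k]]), unclass(all_params[[k]]),
                 ignore_attr = TRUE)
  shipped <- read_cell_params(preset_config_path("cell_params.yaml"))
  expect_equal(unclass(shipped$P), unclass(cell_params("P")),
               ignore_attr = TRUE)
})
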