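test_that("identical configurations give bitwise-identical results", {
  cfg <- short_config(duration_s = 0.5)
  s1 <- simulate_network(cfg)
  s2 <- simulate_network(cfg)
  expect_identical(s1$traces, s2$traces)
  expect_identical(s1$spikes, s2$spikes)
})

test_that("with zero coupling each cell is independent of the others", {
  c1 <- zero_coupling_config(duration_s = 0.8)
  c2 <- zero_coupling_config(duration_s = 0.8,
                             i_ext_cells = list(G = 2, O = 0))
  s1 <- simulate_network(c1)
  s2 <- simulate_network(c2)
  # perturbing G and O leaves every other cell's trace untouched
  for (cl in c("DI", "MS", "MD", "P", "I"))
    expect_identical(s1$traces[, cl], s2$traces[, cl])
  expect_false(identical(s1$traces[, "G"], s2$traces[, "G"]))
})

test_that("numerical blow-up aborts with the offending cell and time", {
  cfg <- zero_coupling_config(duration_s = 0.5,
                              i_ext_cells = list(G = 1e6))
  expect_error(simulate_network(cfg), "blow-up.*cell G")
})

test_that("spike detection counts threshold crossings with a refractory guard", {
  tr <- synthetic_spike_trace(seq(5, 980, by = 25), 1000)  # 40 Hz
  sp <- detect_spikes(tr$v, tr$time)
  expect_length(sp, 40)
  expect_equal(unique(round(compute_isi(sp), 6)), 25)

  flat <- rep(-65, 1000)
  expect_length(detect_spikes(flat, seq_along(flat)), 0)

  # two crossings 1 ms apart merge into one spike
  tr2 <- synthetic_spike_trace(c(100, 101, 150), 200)
  expect_length(detect_spikes(tr2$v, tr2$time), 2)
})

test_that("detected spike count agrees with an independent peak finder", {
  skip_if_not_installed("pracma")
  cfg <- zero_coupling_config(duration_s = 1, i_ext = 1)
  sim <- simulate_network(cfg)
  v <- sim$traces[, "G"]
  pk <- pracma::findpeaks(v, minpeakheight = -20, minpeakdistance = 20)
  expect_equal(length(sim$spikes$G), nrow(pk))
})

test_that("halving the step moves network spike times by < 0.5 ms", {
  cfg <- short_config(duration_s = 1.2, g_nmda_p = 5e-4)
  cfg$record_dt_ms <- 0.1
  fine <- cfg; fine$step_ms <- 0.005; fine$record_dt_ms <- 0.1
  s1 <- simulate_network(cfg)
  s2 <- simulate_network(fine)
  for (cl in c("G", "MS", "P")) {
    a <- s1$spikes[[cl]]; b <- s2$spikes[[cl]]
    n <- min(length(a), length(b))
    expect_gt(n, 0)
    expect_lt(max(abs(a[1:n] - b[1:n])), 0.5, label = paste("spike drift", cl))
  }
})

test_that("without external drive the network is silent for 2 s", {
  cfg <- network_config(duration_s = 2, i_ext = 0)
  sim <- simulate_network(cfg)
  expect_true(all(lengths(sim$spikes) == 0))
})

test_that("traces carry no NaN and share one time grid", {
  sim <- simulate_network(short_config(duration_s = 0.5))
  expect_true(all(is.finite(sim$traces)))
  expect_equal(nrow(sim$traces), length(sim$time))
  expect_equal(colnames(sim$traces), cell_kinds())
})

test_that("simulation outputs serialise to plain-text tables", {
  dir <- withr::local_tempdir()
  sim <- simulate_network(short_config(duration_s = 0.5))
  write_sim(sim, dir)
  expect_true(file.exists(file.path(dir, "traces.csv")))
  tr <- read.csv(file.path(dir, "traces.csv"))
  expect_equal(nrow(tr), length(sim$time))
  sp <- read.csv(file.path(dir, "spikes.csv"))
  expect_equal(nrow(sp), sum(lengths(sim$spikes)))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  expect_equal(meta$method, "rk4")
})

test_that("synaptic gating traces stay within [0, 1] when recorded", {
  sim <- simulate_network(short_config(duration_s = 0.5),
                          record_synapses = TRUE)
  expect_true(all(sim$syn >= 0 & sim$syn <= 1))
  expect_equal(ncol(sim$syn), nrow(sim$edges))
})
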