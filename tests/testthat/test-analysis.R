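test_that("ISI computation equals pairwise differences", {
  expect_equal(compute_isi(c(0, 10, 20)), c(10, 10))
  short <- compute_isi(c(5))
  expect_length(short, 0)
  expect_true(attr(short, "insufficient"))
  set.seed(7)
  sp <- sort(runif(50, 0, 1000))
  oracle <- sp[-1] - sp[-length(sp)]   # brute-force differences
  expect_equal(compute_isi(sp), oracle)
})

test_that("pure sinusoids are recovered within one frequency bin", {
  fs <- 2000
  t <- seq(0, 2, by = 1 / fs)[-1]
  ps <- power_spectrum(sin(2 * pi * 40 * t), fs = fs, window = c(0, 2))
  bin <- fs / (2^ceiling(log2(fs * 4)))
  expect_lt(abs(ps$dominant - 40), bin)
  # dominance by amplitude
  x <- sin(2 * pi * 10 * t) + 3 * sin(2 * pi * 30 * t)
  expect_lt(abs(power_spectrum(x, fs = fs, window = c(0, 2))$dominant - 30), bin)
})

test_that("degenerate spectra are flagged", {
  fs <- 1000
  expect_error(power_spectrum(rnorm(100), fs = fs, window = c(0, 0.1)),
               "shorter")
  flat <- power_spectrum(rep(-65, 2000), fs = fs, window = c(0, 2))
  expect_true(is.na(flat$dominant))
  expect_true(flat$flat)
})

test_that("spectrogram argmax tracks piecewise frequency content", {
  fs <- 1000
  t1 <- seq(0, 2, by = 1 / fs)[-1]
  x <- sin(2 * pi * 40 * t1)
  sg <- spectrogram(x, fs = fs)
  expect_true(all(abs(sg$dominant - 40) < 1))
  y <- c(sin(2 * pi * 20 * t1), sin(2 * pi * 50 * t1))
  sg2 <- spectrogram(y, fs = fs)
  expect_lt(abs(sg2$dominant[1] - 20), 1)
  expect_lt(abs(sg2$dominant[length(sg2$dominant)] - 50), 1)
  expect_true(all(diff(sg2$dominant) >= 0))
  expect_error(spectrogram(x[1:500], fs = fs), "shorter")
})

test_that("zero-lag correlation matches hand computation and Pearson", {
  x <- c(1, 4, 2, 8, 5)
  y <- c(2, 5, 1, 9, 7)
  # term-by-term evaluation of the standardized-product mean
  sx <- sqrt(mean((x - mean(x))^2)); sy <- sqrt(mean((y - mean(y))^2))
  manual <- mean(((x - mean(x)) / sx) * ((y - mean(y)) / sy))
  expect_equal(trace_correlation(x, y), manual)
  expect_equal(trace_correlation(x, y), cor(x, y), tolerance = 1e-12)

  expect_equal(trace_correlation(x, x), 1)
  expect_equal(trace_correlation(x, -x), -1)
  expect_equal(trace_correlation(x, 3 * x + 2), 1)
  expect_warning(r0 <- trace_correlation(x, rep(1, 5)), "variance")
  expect_true(is.na(r0))
  set.seed(11)
  for (i in 1:5) {
    a <- rnorm(100); b <- rnorm(100)
    expect_equal(trace_correlation(a, b), cor(a, b), tolerance = 1e-12)
  }
})

test_that("lagged correlation shifts the second series", {
  set.seed(3)
  a <- rnorm(200)
  b <- c(rnorm(2), a[1:198])   # b trails a by 2 samples: b[i+2] = a[i]
  expect_gt(trace_correlation(a, b, lag = 2), 0.9)
  expect_lt(abs(trace_correlation(a, b, lag = 0)), 0.3)
})

test_that("correlation matrices are symmetric with unit diagonal", {
  sim <- simulate_network(short_config(duration_s = 1))
  m <- correlation_matrix(sim, window = c(0.2, 1))
  expect_equal(unname(diag(m)), rep(1, 7))
  expect_equal(m, t(m))
  expect_true(all(m >= -1 & m <= 1))
})

test_that("correlation summaries group pairs by region", {
  m <- matrix(0.5, 7, 7, dimnames = list(cell_kinds(), cell_kinds()))
  diag(m) <- 1
  s <- correlation_boxplot_summary(rep(list(m), 5))
  expect_equal(nrow(s), choose(7, 2))
  expect_true(all(s$q3 - s$q1 == 0))        # constant across the grid
  expect_equal(s$group[s$pair == "MS-MD"], "within_DG")
  expect_equal(s$group[s$pair == "P-I"], "within_CA3")
  expect_equal(s$group[s$pair == "G-P"], "cross_region")
})

test_that("regime classification follows the operational rules", {
  inter <- classify_regime(rep(30, 20), 17.2)
  expect_equal(inter$label, "interictal")
  pre <- classify_regime(rnorm(30, 27, 1), 37.4)
  expect_equal(pre$label, "preictal")
  burst_isi <- rep(c(8, 9, 10, 120), 8)
  sz <- classify_regime(burst_isi, 51.5)
  expect_equal(sz$label, "seizure_onset")
  expect_true(sz$bursting)
  un <- classify_regime(structure(numeric(), insufficient = TRUE), NA)
  expect_equal(un$label, "unclassified")
})

test_that("burst detection requires bimodal short/long structure", {
  expect_false(is_bursting(rep(30, 50)))
  expect_false(is_bursting(rep(10, 50)))          # fast but regular
  expect_true(is_bursting(rep(c(8, 8, 8, 150), 10)))
})

test_that("a one-point scan reduces to a single-run ISI extraction", {
  cfg <- short_config(duration_s = 1.5)
  scan <- isi_bifurcation_scan(cfg, "g_nmda_p", 0.001, cells = "P")
  sim <- simulate_network(cfg)
  sp <- sim$spikes$P
  sp <- sp[sp >= 200 & sp <= 1500]
  expect_equal(scan$isi, compute_isi(sp))
})

test_that("scans are invariant to grid order", {
  cfg <- short_config(duration_s = 1)
  g <- c(0.001, 0.004)
  s1 <- isi_bifurcation_scan(cfg, "g_nmda_p", g, cells = "P")
  s2 <- isi_bifurcation_scan(cfg, "g_nmda_p", rev(g), cells = "P")
  o1 <- s1[order(s1$value, s1$isi), ]
  o2 <- s2[order(s2$value, s2$isi), ]
  expect_equal(o1$isi, o2$isi)
  expect_equal(o1$value, o2$value)
})

test_that("changepoint detector locates constructed ISI lengthening", {
  vals <- seq(0.001, 0.1, length.out = 12)
  med <- c(rep(60, 5), rep(95, 7)) + rep(c(-1, 1), 6)
  scan <- data.frame(value = rep(vals, each = 3),
                     cell = "MS",
                     isi = rep(med, each = 3))
  class(scan) <- c("dgca3_scan", "data.frame")
  expect_equal(isi_lengthening_point(scan, "MS"), vals[6])
  expect_equal(isi_lengthening_point(scan, "MS", method = "margin"),
               vals[6])
  flat <- scan; flat$isi <- 60
  expect_true(is.na(isi_lengthening_point(flat, "MS")))
})

test_that("bifurcation point is the first burst-structured grid value", {
  tonic <- rep(30, 30)
  bursty <- rep(c(8, 8, 8, 140), 8)
  scan <- data.frame(
    value = c(rep(0.001, 30), rep(0.002, 30), rep(0.004, 32)),
    cell = "P",
    isi = c(tonic, tonic, bursty))
  class(scan) <- c("dgca3_scan", "data.frame")
  expect_equal(bifurcation_point(scan, "P"), 0.004)
})
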