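#' Interspike intervals of a spike train
#'
#' @param spikes Numeric vector of spike times (ms), strictly increasing.
#' @return Numeric vector of consecutive differences (ms).  With fewer
#'   than two spikes an empty vector is returned with attribute
#'   `insufficient = TRUE`.
#' @export
compute_isi <- function(spikes) {
  if (length(spikes) < 2) {
    return(structure(numeric(), insufficient = TRUE))
  }
  stopifnot(all(diff(spikes) > 0))
  diff(spikes)
}

#' Burst structure of an ISI sequence
#'
#' An ISI sequence is burst-structured when it is bimodal in the sense of
#' short intra-burst intervals (< 15 ms) alternating with long inter-burst
#' pauses exceeding three times the median intra-burst interval.
#'
#' @param isi Numeric ISI vector (ms).
#' @return Logical.
#' @export
is_bursting <- function(isi) {
  intra <- isi[isi < 15]
  length(intra) >= 3 && any(isi > 3 * stats::median(intra)) && any(isi > 15)
}

# Welch-averaged one-sided power spectral density; Hann windows, linear
# detrend per segment, zero-padded so bins are finer than 0.25 Hz.
.welch <- function(x, fs, seg_s = 1, overlap = 0.5) {
  L <- round(seg_s * fs)
  stopifnot(length(x) >= L)
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, length(x) - L + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, L - 1) / (L - 1))
  nfft <- 2^ceiling(log2(L * 4))
  tt <- seq_len(L)
  acc <- numeric(nfft %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + L - 1)]
    fit <- stats::lm.fit(cbind(1, tt), seg)
    seg <- fit$residuals * w
    X <- stats::fft(c(seg, numeric(nfft - L)))
    acc <- acc + Mod(X[seq_len(nfft %/% 2 + 1)])^2
  }
  pw <- acc / (length(starts) * fs * sum(w^2))
  pw[2:(length(pw) - 1)] <- 2 * pw[2:(length(pw) - 1)]
  list(freq = seq(0, nfft %/% 2) * fs / nfft, power = pw)
}

.dominant <- function(freq, power, band) {
  sel <- which(freq >= band[1] & freq <= band[2])
  if (!length(sel) || all(power[sel] <= 0)) return(NA_real_)
  freq[sel[which.max(power[sel])]]  # ties resolve to the lower frequency
}

#' Welch power spectrum and dominant frequency of a voltage trace
#'
#' The spectrum is averaged over 1-s Hann windows with 50% overlap,
#' linearly detrended per segment and zero-padded to a sub-0.25-Hz grid.
#' The dominant frequency is the argmax of power over the analysis band
#' (default 1-100 Hz), ties broken toward the lower frequency.
#'
#' @param x Either a numeric trace or a `dgca3_sim` object.
#' @param fs Sampling rate (Hz); taken from the simulation when `x` is a
#'   `dgca3_sim`.
#' @param window Analysis window `c(start, end)` in seconds from trace
#'   onset; must lie inside the trace and span at least 1 s.  Default:
#'   the full trace after a 200-ms transient.
#' @param cell Compartment label when `x` is a simulation.
#' @param band Dominant-frequency search band (Hz).
#' @param seg_s,overlap Welch segment length (s) and fractional overlap.
#' @return List of class `"dgca3_spectrum"`: `freq`, `power`, `dominant`,
#'   `window`, `band`.  A flat trace yields `dominant = NA` with
#'   `flat = TRUE`.
#' @export
power_spectrum <- function(x, fs = NULL, window = NULL, cell = "P",
                           band = c(1, 100), seg_s = 1, overlap = 0.5) {
  if (inherits(x, "dgca3_sim")) {
    fs <- 1000 / x$record_dt_ms
    x <- x$traces[, cell]
  }
  stopifnot(!is.null(fs))
  if (is.null(window)) window <- c(min(0.2, (length(x) / fs) / 2), length(x) / fs)
  i0 <- max(1L, floor(window[1] * fs) + 1L)
  i1 <- min(length(x), ceiling(window[2] * fs))
  if (i1 - i0 + 1 < seg_s * fs) stop("analysis window shorter than one segment")
  seg <- x[i0:i1]
  flat <- stats::var(seg) < 1e-12
  ps <- .welch(seg, fs, seg_s, overlap)
  structure(list(freq = ps$freq, power = ps$power,
                 dominant = if (flat) NA_real_ else .dominant(ps$freq, ps$power, band),
                 window = window, band = band, flat = flat),
            class = "dgca3_spectrum")
}

#' Short-time spectrogram of a voltage trace
#'
#' Sliding-window periodograms (default 1-s Hann windows, 90% overlap);
#' the column-wise argmax over the analysis band traces the dominant
#' frequency through time.
#'
#' @inheritParams power_spectrum
#' @param window_s Window length (s).
#' @param overlap Fractional overlap between consecutive windows.
#' @return List of class `"dgca3_spectrogram"`: `time` (window centres,
#'   s), `freq` (Hz), `power` (freq x time matrix), `dominant` (per
#'   column argmax over `band`).
#' @export
spectrogram <- function(x, fs = NULL, cell = "P", window_s = 1,
                        overlap = 0.9, band = c(1, 100)) {
  if (inherits(x, "dgca3_sim")) {
    fs <- 1000 / x$record_dt_ms
    x <- x$traces[, cell]
  }
  L <- round(window_s * fs)
  if (length(x) < 2 * fs) stop("trace shorter than 2 s")
  if (length(x) < L) stop("trace shorter than one window")
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, length(x) - L + 1L, by = step)
  cols <- lapply(starts, function(s) {
    ps <- .welch(x[s:(s + L - 1)], fs, seg_s = window_s, overlap = 0)
    ps$power
  })
  freq <- .welch(x[seq_len(L)], fs, seg_s = window_s, overlap = 0)$freq
  pw <- do.call(cbind, cols)
  dom <- apply(pw, 2, function(p) .dominant(freq, p, band))
  structure(list(time = (starts - 1 + L / 2) / fs, freq = freq, power = pw,
                 dominant = dom, band = band),
            class = "dgca3_spectrogram")
}

#' Zero-lag linear correlation coefficient of two traces
#'
#' Mean over samples of the product of standardized values,
#' `C_xy(l) = <((x_i - xbar)/sigma_x) ((y_{i+l} - ybar)/sigma_y)>_i`,
#' evaluated at lag `l` in samples (default 0, where it coincides with
#' the Pearson coefficient).
#'
#' @param x,y Equal-length numeric windows.
#' @param lag Delay `l` in samples applied to `y`.
#' @return Coefficient in `[-1, 1]`; `NA` (with a warning) if either
#'   window has zero variance.
#' @export
trace_correlation <- function(x, y, lag = 0) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  i <- seq_len(n - abs(lag))
  xi <- if (lag >= 0) x[i] else x[i + abs(lag)]
  yi <- if (lag >= 0) y[i + lag] else y[i]
  sx <- sqrt(mean((x - mean(x))^2))
  sy <- sqrt(mean((y - mean(y))^2))
  if (sx == 0 || sy == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  mean(((xi - mean(x)) / sx) * ((yi - mean(y)) / sy))
}

#' Zero-lag correlation matrix of all recorded compartments
#'
#' @param sim A [simulate_network()] result.
#' @param window Analysis window `c(start, end)` in seconds; default the
#'   full record after a 200-ms transient.
#' @return Symmetric 7x7 matrix with unit diagonal, class
#'   `"dgca3_cormat"`, with the window stored as an attribute.
#' @export
correlation_matrix <- function(sim, window = NULL) {
  fs <- 1000 / sim$record_dt_ms
  if (is.null(window)) window <- c(0.2, max(sim$time) / 1000)
  i0 <- max(1L, floor(window[1] * fs) + 1L)
  i1 <- min(nrow(sim$traces), ceiling(window[2] * fs))
  sub <- sim$traces[i0:i1, , drop = FALSE]
  k <- ncol(sub)
  m <- diag(1, k)
  dimnames(m) <- list(colnames(sub), colnames(sub))
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    m[a, b] <- m[b, a] <- suppressWarnings(trace_correlation(sub[, a], sub[, b]))
  }
  structure(m, window = window, class = c("dgca3_cormat", "matrix"))
}

.region_of <- c(G = "DG", DI = "DG", MS = "DG", MD = "DG",
                P = "CA3", I = "CA3", O = "CA3")

#' Distribution summaries of pairwise correlations across a sweep
#'
#' @param mats List of [correlation_matrix()] results, one per grid point
#'   of a parameter sweep (at least 5).
#' @return Data frame with one row per unordered cell pair: `pair`,
#'   `cell_a`, `cell_b`, `group` (`within_DG`, `within_CA3`,
#'   `cross_region`), `median`, `q1`, `q3`, `n`.
#' @export
correlation_boxplot_summary <- function(mats) {
  stopifnot(length(mats) >= 5)
  cells <- colnames(mats[[1]])
  out <- list()
  for (a in seq_along(cells)[-length(cells)]) for (b in (a + 1):length(cells)) {
    vals <- vapply(mats, function(m) m[a, b], numeric(1))
    qs <- stats::quantile(vals, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    ra <- .region_of[[cells[a]]]; rb <- .region_of[[cells[b]]]
    grp <- if (ra == rb) paste0("within_", ra) else "cross_region"
    out[[length(out) + 1]] <- data.frame(
      pair = paste(cells[a], cells[b], sep = "-"),
      cell_a = cells[a], cell_b = cells[b], group = grp,
      median = qs[2], q1 = qs[1], q3 = qs[3], n = length(vals))
  }
  do.call(rbind, out)
}

#' Classify the discharge regime of one analysis window
#'
#' Operational rules: a burst-structured ISI sequence (see
#' [is_bursting()]) marks seizure onset; tonic spiking with a dominant
#' frequency at or above the low-gamma edge (28 Hz) marks the preictal
#' regime; tonic spiking with median ISI in the 20-50 ms interictal band
#' and a sub-gamma dominant frequency is interictal; anything else
#' (including fewer than two spikes) is unclassified.
#'
#' @param isi ISI sequence (ms), e.g. from [compute_isi()].
#' @param spectrum A `"dgca3_spectrum"` for the same window (or a number,
#'   read as the dominant frequency in Hz).
#' @return List of class `"dgca3_regime"`: `label`, `median_isi`,
#'   `bursting`, `dominant`.
#' @export
classify_regime <- function(isi, spectrum) {
  dom <- if (inherits(spectrum, "dgca3_spectrum")) spectrum$dominant else spectrum
  if (length(isi) < 1 || isTRUE(attr(isi, "insufficient"))) {
    return(structure(list(label = "unclassified", median_isi = NA_real_,
                          bursting = FALSE, dominant = dom),
                     class = "dgca3_regime"))
  }
  med <- stats::median(isi)
  burst <- is_bursting(isi)
  label <- if (burst) "seizure_onset"
  else if (!is.na(dom) && dom >= 28) "preictal"
  else if (med >= 20 && med <= 50) "interictal"
  else "unclassified"
  structure(list(label = label, median_isi = med, bursting = burst,
                 dominant = dom), class = "dgca3_regime")
}

.sweep_params <- c("g_nmda_p", "g_p_ms", "g_p_di")

# One simulation per grid value; returns spikes and dominant frequencies
# without retaining traces.  Failed integrations are recorded as missing.
.sweep <- function(config, parameter, grid, cells = cell_kinds(),
                   window = NULL, transient_s = 0.2) {
  stopifnot(parameter %in% .sweep_params)
  lapply(grid, function(val) {
    cfg <- config
    cfg[[parameter]] <- val
    res <- tryCatch(simulate_network(cfg), error = function(e) e)
    if (inherits(res, "error")) {
      return(list(value = val, ok = FALSE, message = conditionMessage(res)))
    }
    dur <- cfg$duration_s
    win <- window %||% c(transient_s, dur)
    spikes <- lapply(res$spikes[cells],
                     function(s) s[s >= win[1] * 1000 & s <= win[2] * 1000])
    dom <- vapply(cells, function(cl) {
      if (diff(win) < 1) return(NA_real_)   # spectra need >= 1-s windows
      power_spectrum(res, cell = cl, window = win)$dominant
    }, numeric(1))
    cors <- correlation_matrix(res, window = win)
    list(value = val, ok = TRUE, spikes = spikes, dominant = dom, cors = cors)
  })
}

#' ISI bifurcation scan over a synaptic conductance
#'
#' Runs one full deterministic simulation per grid value and extracts the
#' post-transient ISI sequence of each requested cell, the raw material of
#' an ISI-versus-parameter bifurcation diagram.
#'
#' @param config Base [network_config()].
#' @param parameter One of `"g_nmda_p"`, `"g_p_ms"`, `"g_p_di"`.
#' @param grid Numeric vector of parameter values.
#' @param cells Compartment labels to analyse.
#' @param window Analysis window `c(start, end)` in seconds (default:
#'   after a 200-ms transient to the end).
#' @return Data frame `value, cell, isi` (long form) of class
#'   `"dgca3_scan"`; aborted grid points are flagged in
#'   `attr(, "missing")` and skipped.
#' @export
isi_bifurcation_scan <- function(config, parameter, grid,
                                 cells = "P", window = NULL) {
  runs <- .sweep(config, parameter, grid, cells = cells, window = window)
  missing <- grid[!vapply(runs, `[[`, logical(1), "ok")]
  rows <- lapply(runs, function(r) {
    if (!r$ok) return(NULL)
    do.call(rbind, lapply(names(r$spikes), function(cl) {
      isi <- compute_isi(r$spikes[[cl]])
      if (!length(isi)) return(NULL)
      data.frame(value = r$value, cell = cl, isi = isi)
    }))
  })
  out <- do.call(rbind, rows) %||% data.frame(value = numeric(),
                                              cell = character(),
                                              isi = numeric())
  structure(out, missing = missing, parameter = parameter,
            class = c("dgca3_scan", "data.frame"))
}

#' Dominant-frequency curves over a parameter sweep
#'
#' One simulation per grid value with identical analysis windows; the
#' dominant frequency of every requested compartment is extracted from
#' its Welch spectrum.
#'
#' @inheritParams isi_bifurcation_scan
#' @return Data frame `value, cell, dominant` (Hz); aborted grid points
#'   flagged in `attr(, "missing")`.
#' @export
dominant_frequency_sweep <- function(config, parameter, grid,
                                     cells = cell_kinds(), window = NULL) {
  runs <- .sweep(config, parameter, grid, cells = cells, window = window)
  missing <- grid[!vapply(runs, `[[`, logical(1), "ok")]
  rows <- lapply(runs, function(r) {
    if (!r$ok) return(NULL)
    data.frame(value = r$value, cell = names(r$dominant),
               dominant = unname(r$dominant))
  })
  out <- do.call(rbind, rows)
  structure(out, missing = missing, parameter = parameter,
            class = c("dgca3_sweep", "data.frame"))
}

#' First grid value at which a cell's ISI pattern turns burst-structured
#'
#' @param scan A [isi_bifurcation_scan()] result.
#' @param cell Compartment label.
#' @return The smallest swept value whose ISI sequence satisfies
#'   [is_bursting()], or `NA` if none does.
#' @export
bifurcation_point <- function(scan, cell = "P") {
  vals <- sort(unique(scan$value[scan$cell == cell]))
  for (v in vals) {
    if (is_bursting(scan$isi[scan$value == v & scan$cell == cell])) return(v)
  }
  NA_real_
}

#' Critical point at which a cell's ISI begins to lengthen
#'
#' Estimates where, along a conductance sweep, a cell's median ISI
#' switches from its low-conductance baseline to a sustained higher
#' level.  The default method fits a two-segment (changepoint) model to
#' the median-ISI-versus-parameter curve and returns the first grid
#' value of the high segment, requiring that the upper segment mean
#' exceed the baseline mean; this is robust to the exact margin chosen.
#' The `"margin"` method instead returns the smallest grid value from
#' which the median ISI stays above `factor` times the baseline (median
#' of the first `baseline_n` points) for every larger value.
#'
#' @param scan A [isi_bifurcation_scan()] result.
#' @param cell Compartment label.
#' @param method `"changepoint"` (default) or `"margin"`.
#' @param baseline_n Leading grid points defining the baseline
#'   (`"margin"` method).
#' @param factor Sustained-margin multiplier (`"margin"` method).
#' @return Critical parameter value, or `NA` if the ISI never lengthens.
#' @export
isi_lengthening_point <- function(scan, cell = "MS",
                                  method = c("changepoint", "margin"),
                                  baseline_n = 3, factor = 1.25) {
  method <- match.arg(method)
  vals <- sort(unique(scan$value[scan$cell == cell]))
  med <- vapply(vals, function(v)
    stats::median(scan$isi[scan$value == v & scan$cell == cell]), numeric(1))
  n <- length(vals)
  if (n < 4) return(NA_real_)
  if (method == "changepoint") {
    sse <- function(x) sum((x - mean(x))^2)
    best <- NA_real_
    best_sse <- sse(med)
    for (k in 3:(n - 1)) {
      lo <- med[1:(k - 1)]; hi <- med[k:n]
      if (mean(hi) <= mean(lo)) next
      s <- sse(lo) + sse(hi)
      if (s < best_sse) { best_sse <- s; best <- vals[k] }
    }
    return(best)
  }
  base <- stats::median(med[seq_len(min(baseline_n, n))])
  above <- med > factor * base
  sus <- rev(cumprod(rev(above))) > 0  # above here and at every larger value
  if (!any(sus)) return(NA_real_)
  vals[which(sus)[1]]
}
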