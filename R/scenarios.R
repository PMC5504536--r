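#' Define a sweep scenario
#'
#' A scenario bundles a base configuration, the conductance to sweep,
#' the grid, and the analysis windows, so that a whole experiment family
#' is reproducible from one object.
#'
#' @param name Scenario label.
#' @param config Base [network_config()].
#' @param parameter Swept conductance (`"g_nmda_p"`, `"g_p_ms"`,
#'   `"g_p_di"`).
#' @param grid Strictly increasing numeric grid.
#' @param cells Compartments analysed.
#' @param window Analysis window `c(start, end)` (s); `NULL` means after
#'   the 200-ms transient to the end.
#' @return Object of class `"dgca3_scenario"`.
#' @export
scenario <- function(name, config, parameter, grid,
                     cells = cell_kinds(), window = NULL) {
  stopifnot(parameter %in% .sweep_params,
            length(grid) >= 1, all(diff(grid) > 0))
  viol <- validate_config(config)
  if (length(viol)) stop("invalid config: ", paste(viol, collapse = "; "))
  structure(list(name = name, config = config, parameter = parameter,
                 grid = grid, cells = cells, window = window),
            class = "dgca3_scenario")
}

#' Preset: NMDA-conductance sweep of the mossy-to-pyramidal pathway
#'
#' Mode-A network with a weak backprojection (`g_p_ms = 1e-4`), sweeping
#' `g_nmda_p` over a log-spaced grid.  This is the experiment in which the
#' pyramidal cell walks through interictal, preictal and seizure-onset
#' discharge regimes.
#'
#' @param from,to,n Grid endpoints (relative conductance) and size.
#' @param duration_s Per-run simulated time (s).
#' @return A [scenario()].
#' @export
preset_nmda_sweep <- function(from = 5e-4, to = 0.1, n = 25,
                              duration_s = 10) {
  cfg <- network_config(backprojection = "mossy_soma", g_p_ms = 1e-4,
                        duration_s = duration_s)
  scenario("nmda_sweep", cfg, "g_nmda_p",
           exp(seq(log(from), log(to), length.out = n)))
}

#' Preset: glutamatergic backprojection sweep (pyramidal to mossy soma)
#'
#' Mode-A network with `g_nmda_p = 0.001`, sweeping the backprojection
#' conductance `g_p_ms` linearly.
#'
#' @inheritParams preset_nmda_sweep
#' @return A [scenario()].
#' @export
preset_glut_backprojection <- function(from = 1e-4, to = 0.01, n = 20,
                                       duration_s = 10) {
  cfg <- network_config(backprojection = "mossy_soma", g_nmda_p = 0.001,
                        duration_s = duration_s)
  scenario("glut_backprojection", cfg, "g_p_ms",
           seq(from, to, length.out = n))
}

#' Preset: GABAergic backprojection sweep (pyramidal to DG interneuron)
#'
#' Mode-B network with `g_nmda_p = 0.001`, sweeping `g_p_di` linearly.
#'
#' @inheritParams preset_nmda_sweep
#' @return A [scenario()].
#' @export
preset_gaba_backprojection <- function(from = 0.001, to = 0.1, n = 20,
                                       duration_s = 10) {
  cfg <- network_config(backprojection = "dg_interneuron",
                        g_nmda_p = 0.001, duration_s = duration_s)
  scenario("gaba_backprojection", cfg, "g_p_di",
           seq(from, to, length.out = n))
}

#' Run a scenario and write its analysis tables
#'
#' Executes one deterministic simulation per grid value and writes, under
#' `out_dir`: `isi.csv` (long ISI table), `dominant_frequency.csv`,
#' `correlations.csv` (pairwise zero-lag coefficients per grid value),
#' `regimes.csv` (per-point regime labels for the pyramidal cell) and a
#' `manifest.json` listing files, grid, and any failed grid points.
#'
#' @param sc A [scenario()].
#' @param out_dir Output directory.
#' @return Invisibly, the manifest as a list.
#' @export
run_scenario <- function(sc, out_dir) {
  stopifnot(inherits(sc, "dgca3_scenario"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  runs <- .sweep(sc$config, sc$parameter, sc$grid, cells = sc$cells,
                 window = sc$window)
  ok <- vapply(runs, `[[`, logical(1), "ok")
  good <- runs[ok]

  isi_tab <- do.call(rbind, lapply(good, function(r)
    do.call(rbind, lapply(names(r$spikes), function(cl) {
      isi <- compute_isi(r$spikes[[cl]])
      if (!length(isi)) return(NULL)
      data.frame(value = r$value, cell = cl, isi = isi)
    })))) %||% data.frame()
  dom_tab <- do.call(rbind, lapply(good, function(r)
    data.frame(value = r$value, cell = names(r$dominant),
               dominant = unname(r$dominant)))) %||% data.frame()
  cor_tab <- do.call(rbind, lapply(good, function(r) {
    m <- r$cors
    idx <- which(upper.tri(m), arr.ind = TRUE)
    data.frame(value = r$value,
               cell_a = rownames(m)[idx[, 1]], cell_b = colnames(m)[idx[, 2]],
               cxy = m[idx])
  })) %||% data.frame()
  reg_tab <- do.call(rbind, lapply(good, function(r) {
    if (!"P" %in% names(r$spikes)) return(NULL)
    isi <- compute_isi(r$spikes[["P"]])
    reg <- classify_regime(isi, r$dominant[["P"]])
    data.frame(value = r$value, label = reg$label,
               median_isi = reg$median_isi, bursting = reg$bursting,
               dominant = reg$dominant)
  })) %||% data.frame()

  files <- c(isi = "isi.csv", dominant = "dominant_frequency.csv",
             correlations = "correlations.csv", regimes = "regimes.csv")
  utils::write.csv(isi_tab, file.path(out_dir, files["isi"]), row.names = FALSE)
  utils::write.csv(dom_tab, file.path(out_dir, files["dominant"]), row.names = FALSE)
  utils::write.csv(cor_tab, file.path(out_dir, files["correlations"]), row.names = FALSE)
  utils::write.csv(reg_tab, file.path(out_dir, files["regimes"]), row.names = FALSE)

  manifest <- list(scenario = sc$name, parameter = sc$parameter,
                   grid = sc$grid, files = as.list(files),
                   complete = all(ok),
                   missing_points = sc$grid[!ok],
                   failures = lapply(runs[!ok], function(r)
                     list(value = r$value, message = r$message)),
                   backprojection = sc$config$backprojection,
                   g_nmda_p = sc$config$g_nmda_p,
                   duration_s = sc$config$duration_s,
                   syn_gain = sc$config$syn_gain)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Compare the two backprojection modes
#'
#' Reads the dominant-frequency tables of two completed scenario runs and
#' tabulates, per compartment, the frequency change across each sweep and
#' its monotone trend.  The glutamatergic run is flagged net-excitatory
#' when the mossy and pyramidal frequencies trend upward; the GABAergic
#' run net-suppressive when they trend downward.
#'
#' @param dir_a,dir_b Output directories of [run_scenario()] for the
#'   mossy-soma and DG-interneuron backprojection sweeps.
#' @return List with `table` (per-cell deltas and trends) and the two
#'   flags `a_net_excitatory`, `b_net_suppressive`.
#' @export
compare_backprojections <- function(dir_a, dir_b) {
  read_run <- function(dir) {
    man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                               simplifyVector = TRUE)
    if (!isTRUE(man$complete)) stop("incomplete manifest in ", dir)
    list(man = man,
         dom = utils::read.csv(file.path(dir, man$files$dominant)))
  }
  a <- read_run(dir_a); b <- read_run(dir_b)
  summarise <- function(dom) {
    cells <- unique(dom$cell)
    do.call(rbind, lapply(cells, function(cl) {
      d <- dom[dom$cell == cl, ]
      d <- d[order(d$value), ]
      trend <- if (nrow(d) >= 3)
        suppressWarnings(stats::cor(d$value, d$dominant, method = "spearman",
                                    use = "complete.obs"))
      else NA_real_
      data.frame(cell = cl, first = d$dominant[1],
                 last = d$dominant[nrow(d)],
                 delta = d$dominant[nrow(d)] - d$dominant[1],
                 trend = trend)
    }))
  }
  ta <- summarise(a$dom); tb <- summarise(b$dom)
  tab <- merge(ta, tb, by = "cell", suffixes = c("_a", "_b"))
  key <- c("MS", "P")
  a_exc <- all(tab$delta_a[tab$cell %in% key] >= 0) &&
    all(is.na(tab$trend_a[tab$cell %in% key]) |
          tab$trend_a[tab$cell %in% key] >= 0)
  b_sup <- all(tab$delta_b[tab$cell %in% key] <= 0) &&
    all(is.na(tab$trend_b[tab$cell %in% key]) |
          tab$trend_b[tab$cell %in% key] <= 0)
  list(table = tab,
       a_net_excitatory = if (nrow(a$dom) > length(unique(a$dom$cell))) a_exc else NA,
       b_net_suppressive = if (nrow(b$dom) > length(unique(b$dom$cell))) b_sup else NA)
}
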