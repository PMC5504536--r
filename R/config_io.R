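#' Read and write network configurations as YAML
#'
#' A configuration serialises to a flat YAML document whose keys mirror
#' the arguments of [network_config()]; reading re-validates the result.
#'
#' @param path File path.
#' @return [read_network_config()] returns a `dgca3_config`;
#'   [write_network_config()] invisibly returns `path`.
#' @export
read_network_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(network_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg <- do.call(network_config, raw)
  viol <- validate_config(cfg)
  if (length(viol)) stop("invalid config in ", path, ": ",
                         paste(viol, collapse = "; "))
  cfg
}

#' @rdname read_network_config
#' @param config A [network_config()] object.
#' @export
write_network_config <- function(config, path) {
  stopifnot(inherits(config, "dgca3_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read and write cell parameter sets as YAML
#'
#' One named block per cell kind (`G`, `DI`, `mossy`, `P`, `I`, `O`).
#' The packaged file `extdata/cell_params.yaml` records the shipped
#' default parameterisation.
#'
#' @param path File path.
#' @return [read_cell_params()] returns a named list of
#'   [cell_params()] objects.
#' @export
read_cell_params <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(k) {
    p <- cell_params(k)
    unknown <- setdiff(names(raw[[k]]), names(p))
    if (length(unknown))
      stop("unknown parameter(s) for ", k, ": ", paste(unknown, collapse = ", "))
    p[names(raw[[k]])] <- raw[[k]]
    structure(p, kind = k, class = "dgca3_cell_params")
  })
  stats::setNames(out, names(raw))
}

#' @rdname read_cell_params
#' @param params Named list of [cell_params()] objects.
#' @export
write_cell_params <- function(params, path) {
  yaml::write_yaml(lapply(params, function(p) lapply(unclass(p), identity)),
                   path)
  invisible(path)
}

#' Path to a packaged preset configuration
#'
#' @param name File name under the package's `extdata/`, e.g.
#'   `"nmda_sweep.yaml"`; with no argument, lists the available presets.
#' @return Full path (or a vector of file names).
#' @export
preset_config_path <- function(name = NULL) {
  dir <- system.file("extdata", package = "dgca3net")
  if (is.null(name)) return(list.files(dir, pattern = "\\.yaml$"))
  p <- file.path(dir, name)
  if (!file.exists(p)) stop("no packaged preset '", name, "'")
  p
}
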