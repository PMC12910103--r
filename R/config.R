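.CONFIG_DEFAULTS <- list(
  threshold_db = -70, surface_offset_m = 10, integration_distance_nmi = 0.1,
  depth_bin_m = 1, diel_altitude_deg = 18, k_range = c(2L, 8L),
  rng_seed = 1L, cluster_unit = "per_day", min_cells = 5L, n_init = 20L,
  jaccard_min = 0.25)

#' Build a pipeline configuration
#'
#' Defaults follow the standard processing constants: a -70 dB extraction
#' threshold, a 10 m surface exclusion, 0.1 nmi by 1 m echo-integration
#' cells, and day/night separated at +-18 degrees solar altitude (the
#' astronomical-twilight bound). Segmentation keeps components of at least
#' `min_cells` cells; cross-frequency layers match at Jaccard overlap
#' `jaccard_min`.
#'
#' @param ... named overrides of any default (see [PipelineConfig]).
#' @return a validated [PipelineConfig].
#' @export
#' @examples
#' pipelineConfig(threshold_db = -65)
pipelineConfig <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(.CONFIG_DEFAULTS))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  vals <- utils::modifyList(.CONFIG_DEFAULTS, over)
  for (nm in names(vals)) {
    proto <- .CONFIG_DEFAULTS[[nm]]
    if (is.numeric(proto) && !is.numeric(vals[[nm]]))
      stop(sprintf("configuration key '%s' must be numeric", nm))
    if (is.character(proto) && !is.character(vals[[nm]]))
      stop(sprintf("configuration key '%s' must be character", nm))
  }
  new("PipelineConfig",
      threshold_db = as.numeric(vals$threshold_db),
      surface_offset_m = as.numeric(vals$surface_offset_m),
      integration_distance_nmi = as.numeric(vals$integration_distance_nmi),
      depth_bin_m = as.numeric(vals$depth_bin_m),
      diel_altitude_deg = as.numeric(vals$diel_altitude_deg),
      k_range = as.integer(vals$k_range),
      rng_seed = as.integer(vals$rng_seed),
      cluster_unit = vals$cluster_unit,
      min_cells = as.integer(vals$min_cells),
      n_init = as.integer(vals$n_init),
      jaccard_min = as.numeric(vals$jaccard_min))
}

#' Load a configuration file
#'
#' Reads a YAML key-value file, applies defaults for absent keys, rejects
#' unknown keys (typo guard) and type mismatches, and logs the fully
#' resolved configuration. An empty file yields all defaults.
#'
#' @param path YAML file path.
#' @return a validated [PipelineConfig].
#' @seealso [pipelineConfig()]
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) stop("configuration file must be a YAML mapping")
  cfg <- do.call(pipelineConfig, vals)
  .log("resolved config: %s",
       paste(vapply(slotNames(cfg), function(s)
         sprintf("%s=%s", s, paste(slot(cfg, s), collapse = "..")),
         character(1)), collapse = " "))
  cfg
}

# Config as a plain named list (manifest snapshots, YAML round-trip).
.configAsList <- function(cfg) {
  out <- lapply(slotNames(cfg), function(s) slot(cfg, s))
  names(out) <- slotNames(cfg)
  out
}
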