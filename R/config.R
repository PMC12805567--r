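#' @useDynLib memorient, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Default configuration
#'
#' All tunable parameters of the orientation and cell-wall pipelines with
#' their defaults; a YAML config file overrides any subset.
#'
#' @return nested list of defaults.
#' @export
default_config <- function() {
  list(
    membrane = list(core_half_width = 1.4, head_width = 0.6,
                    smoothing_width = 0.25, tail_type = "C1",
                    head_type = "Na", leaflet_charge_density = c(0, 0),
                    coulomb_cutoff = 3, dielectric_scale = 15),
    orient = list(n_grid = 36, n_iters = 150, n_probes = 32,
                  t_z = 0.3, t_ang = 8, lambda = 2,
                  positive_inside_density = -0.02,
                  peripheral = list(n_grid = 72, n_iters = 300)),
    surface = list(batch_size = 512, stop_fraction = 0.01,
                   occupancy_radius = 0.264),
    pg_predict = list(pg_type = "Nda", pg_half_width = 1.0,
                      pg_sheet_density = -0.3, bias_strength = 50,
                      slab_thickness = 2),
    pg_build = list(strand_spacing = 2, unit_length = 1, layer_spacing = 2,
                    K_t = 0.05, P_cl = 0.5, P_l = 0, P_o = 0, reach = 2.2,
                    mcmc_steps = 20000)
  )
}

#' Load a configuration, overlaying a YAML file on the defaults
#'
#' @param path YAML file or NULL for pure defaults.
#' @return nested list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
    cfg <- utils::modifyList(cfg, yaml::read_yaml(path))
  }
  cfg
}

#' Print the effective configuration as YAML
#'
#' @param path optional YAML overrides.
#' @return the config, invisibly.
#' @export
dump_config <- function(path = NULL) {
  cfg <- load_config(path)
  cat(yaml::as.yaml(cfg))
  invisible(cfg)
}
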