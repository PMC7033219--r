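# Configuration: a nested list with blocks gait / muscles / ligaments /
# material / geometry / solver / sweep, read from YAML and merged over the
# defaults.

#' Default model configuration
#'
#' All tunable parameters of the workflow with their default values. Tissue
#' material values are literature-typical placeholders for articular
#' cartilage, not subject-specific measurements.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    gait = list(n_grid = 101, emg_band_hz = c(20, 450), emg_lp_hz = 6,
                emg_norm = "trial-max"),
    muscles = list(band = 0.1, floor = 0.02, table = NULL),
    ligaments = list(
      ACL = list(K_l = 10, prestrain_pct = 8, n_elements = 60),
      PCL = list(K_l = 18, prestrain_pct = -13.5, n_elements = 100),
      LCL = list(K_l = 6, prestrain_pct = -7.33, n_elements = 15),
      MCL = list(K_l = 8.25, prestrain_pct = 3.66, n_elements = 20)),
    material = list(E_m = 0.5, nu_m = 0.15, E_0 = 2, E_eps = 500, eta = 0,
                    k_0 = 2e-15, M_k = 5, e_0 = 4, n_nodes = 8, chi = 0.9),
    geometry = list(),
    solver = list(stance_duration_s = 0.6, tol_rel = 1e-9),
    sweep = list(offsets_pct = c(-10, -5, 0, 5, 10),
                 ligaments = c("ACL", "PCL", "LCL", "MCL")))
}

#' Read a configuration file
#'
#' Reads a YAML configuration and merges it over
#' \code{\link{default_config}}.
#'
#' @param path YAML file path (NULL returns the defaults).
#' @return Nested named list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_knee("config file not found: %s", path)
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}
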