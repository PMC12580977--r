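#' Run configuration
#'
#' Reads and validates a JSON or YAML run configuration controlling
#' simulation and analysis defaults. Unknown keys are rejected. Recognized
#' keys:
#' \describe{
#'   \item{`conditions`}{list of records (each with `lipid`, `scaffold`
#'     and any [lipid_conditions()] column) overriding the packaged
#'     condition table.}
#'   \item{`grids`}{named list mapping a lipid to `[min, max, step]`
#'     temperature grids, degrees C.}
#'   \item{`seed`}{integer base seed.}
#'   \item{`noise_sd`}{overrides the condition table's noise level.}
#'   \item{`scale`}{intensity scale for the generator.}
#'   \item{`derivative`}{sub-keys `smooth_window`, `refine_peak`,
#'     `include_endpoints`, `interpolate`.}
#'   \item{`boundary`}{sub-keys `variant`, `width`.}
#' }
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A validated config list of class `"run_config"`, with defaults
#'   filled in.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop_typed("laurdanGP_config_error", paste("no such config file:", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    stop_typed("laurdanGP_config_error",
               "config must be a .json, .yaml or .yml file")
  }
  resolve_run_config(raw)
}

run_config_defaults <- function() {
  list(conditions = NULL, grids = NULL, seed = 1L, noise_sd = NULL,
       scale = 1000,
       derivative = list(smooth_window = NULL, refine_peak = FALSE,
                         include_endpoints = FALSE, interpolate = FALSE),
       boundary = list(variant = "radius-ratio", width = 1.25))
}

resolve_run_config <- function(raw) {
  defaults <- run_config_defaults()
  raw <- as.list(raw)
  bad <- setdiff(names(raw), names(defaults))
  if (length(bad))
    stop_typed("laurdanGP_config_error",
               paste("unknown config key(s):", paste(bad, collapse = ", ")))
  for (sub in c("derivative", "boundary")) {
    if (!is.null(raw[[sub]])) {
      extra <- setdiff(names(raw[[sub]]), names(defaults[[sub]]))
      if (length(extra))
        stop_typed("laurdanGP_config_error",
                   sprintf("unknown config key(s) under '%s': %s", sub,
                           paste(extra, collapse = ", ")))
    }
  }
  cfg <- utils::modifyList(defaults, raw)
  if (!is.null(cfg$conditions) && !is.data.frame(cfg$conditions))
    cfg$conditions <- do.call(rbind, lapply(cfg$conditions, as.data.frame))
  structure(cfg, class = "run_config")
}

config_conditions <- function(cfg) {
  lipid_conditions(overrides = cfg$conditions)
}

config_grid <- function(cfg, lipid) {
  g <- cfg$grids[[lipid]]
  if (is.null(g)) return(default_temperature_grid(lipid))
  if (length(g) != 3L)
    stop_typed("laurdanGP_config_error",
               sprintf("grid for '%s' must be [min, max, step]", lipid))
  seq(g[[1L]], g[[2L]], by = g[[3L]])
}
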