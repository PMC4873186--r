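## Run configuration: a flat key-value (YAML) file over the experiment
## parameters, with validation, defaults equal to the standard stimulus /
## population values, and a manifest-writing runner.

config_fields <- function() {
  list(experiment = list(type = "character",
                         default = "correlation_disparity",
                         allowed = c("stimgen", "tuning", "density_sweep",
                                     "refresh_sweep", "population_tuning",
                                     "correlation_disparity",
                                     "correlation_refresh", "dot_size",
                                     "alternation")),
       seed = list(type = "integer", default = 1L),
       scale = list(type = "numeric", default = 1, min = 1e-3, max = 1),
       out_dir = list(type = "character", default = "results"),
       field_size_px = list(type = "integer", default = 292L, min = 4),
       deg_per_px = list(type = "numeric", default = 0.03, min = 1e-6),
       dot_radius_deg = list(type = "numeric", default = 0.09, min = 1e-6),
       density = list(type = "numeric", default = 0.24, min = 0),
       disparity_deg = list(type = "numeric", default = 0.03),
       match_level = list(type = "numeric", default = 1, min = 0, max = 1),
       disk_diameter_deg = list(type = "numeric", default = 2.5, min = 1e-6),
       annulus_width_deg = list(type = "numeric", default = 1, min = 0),
       surround_mode = list(type = "character", default = "correlated",
                            allowed = c("correlated", "same_as_center")),
       refresh_rate_hz = list(type = "numeric", default = 21.25, min = 1e-6),
       duration_s = list(type = "numeric", default = 1.5, min = 1e-6),
       alternation_rate_hz = list(type = "numeric", default = NA_real_),
       kernel = list(type = "character", default = "biphasic",
                     allowed = c("biphasic", "lowpass", "none")),
       exponent = list(type = "integer", default = 2L, min = 1, max = 2),
       kappa = list(type = "numeric", default = NA_real_, min = 0),
       target_accuracy = list(type = "numeric", default = 0.95,
                              min = 0.51, max = 0.999),
       n_trials = list(type = "integer", default = 1000L, min = 2),
       n_patterns = list(type = "integer", default = 1000L, min = 1))
}

#' Build a validated run configuration
#'
#' All fields default to the standard stimulus and population values
#' (292 px field at 0.03 deg/px, 0.09-degree dots at 24% density, ...);
#' unknown fields and out-of-range values are rejected with the offending
#' field named.
#'
#' @param ... Field overrides (see [load_run_config()] for the field
#'   list).
#' @return An object of class `run_config`.
#' @examples
#' run_config(experiment = "tuning", n_patterns = 100)
#' @export
run_config <- function(...) {
  user <- list(...)
  spec <- config_fields()
  unknown <- setdiff(names(user), names(spec))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg <- lapply(spec, `[[`, "default")
  overridden <- character(0)
  for (nm in names(user)) {
    val <- user[[nm]]
    fs <- spec[[nm]]
    if (fs$type == "integer") {
      if (!is.numeric(val) || length(val) != 1 ||
          (is.finite(val) && val != round(val)))
        stop("config field '", nm, "' must be a single integer")
      val <- as.integer(val)
    } else if (fs$type == "numeric") {
      if (!is.numeric(val) || length(val) != 1)
        stop("config field '", nm, "' must be a single number")
      val <- as.numeric(val)
    } else {
      if (!is.character(val) || length(val) != 1)
        stop("config field '", nm, "' must be a single string")
    }
    if (!is.null(fs$allowed) && !val %in% fs$allowed)
      stop("config field '", nm, "' must be one of: ",
           paste(fs$allowed, collapse = ", "))
    if (!is.null(fs$min) && is.finite(val) && val < fs$min)
      stop("config field '", nm, "' must be >= ", fs$min)
    if (!is.null(fs$max) && is.finite(val) && val > fs$max)
      stop("config field '", nm, "' must be <= ", fs$max)
    cfg[[nm]] <- val
    overridden <- c(overridden, nm)
  }
  structure(cfg, overridden = overridden, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration (", x$experiment, ")\n", sep = "")
  for (nm in names(x))
    cat(sprintf("  %-20s %s%s\n", nm, format(x[[nm]]),
                if (nm %in% attr(x, "overridden")) "  [override]" else ""))
  invisible(x)
}

#' Load a run configuration from a YAML file
#'
#' The file is a flat key-value mapping over the fields of
#' [run_config()]; missing fields take the standard defaults, unknown
#' keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config file must be a key-value mapping")
  do.call(run_config, raw)
}

#' Write a run configuration to a YAML file
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg)[names(config_fields())], path)
  invisible(path)
}

cfg_stim_params <- function(cfg) {
  stim_params(field_size_px = cfg$field_size_px,
              deg_per_px = cfg$deg_per_px,
              dot_radius_deg = cfg$dot_radius_deg,
              density = cfg$density,
              disparity_deg = cfg$disparity_deg,
              match_level = cfg$match_level,
              disk_diameter_deg = cfg$disk_diameter_deg,
              annulus_width_deg = cfg$annulus_width_deg,
              surround_mode = cfg$surround_mode,
              refresh_rate_hz = cfg$refresh_rate_hz,
              duration_s = cfg$duration_s)
}

#' Execute a configured experiment run
#'
#' Runs the configured experiment with the configured seed, writes the
#' tabular result as CSV and a JSON manifest (full configuration, seed,
#' package version, wall-clock time) into the output directory, and
#' returns the result invisibly.  Identical configuration and seed give
#' byte-identical CSV output.
#'
#' @param cfg A `run_config` (or path to a YAML config file).
#' @return The experiment result, invisibly; paths are recorded in
#'   attribute `"paths"`.
#' @export
run_experiment <- function(cfg) {
  if (is.character(cfg)) cfg <- load_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  if (!dir.exists(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE)
    message("created output directory: ", cfg$out_dir)
  }
  t0 <- Sys.time()
  set.seed(cfg$seed)
  sp <- cfg_stim_params(cfg)
  n_tr <- max(2L, as.integer(round(cfg$n_trials * cfg$scale)))
  n_pat <- max(1L, as.integer(round(cfg$n_patterns * cfg$scale)))
  kern <- if (cfg$kernel == "none") NULL else temporal_kernel(kind = cfg$kernel)
  res <- switch(cfg$experiment,
    stimgen = {
      s <- if (!is.na(cfg$alternation_rate_hz))
        make_alternating_rds(alternation_params(sp, cfg$alternation_rate_hz))
      else make_dynamic_rds(sp)
      write_stimulus(s, cfg$out_dir, "stim")
      data.frame(n_frames = dim(s$left)[3],
                 mean_correlation = mean(binocular_pixel_correlation(s),
                                         na.rm = TRUE))
    },
    tuning = {
      u <- bem_unit(dx = 0.1, sigma = 0.1, kernel = kern)
      as.data.frame(tuning_curve(u, sp, n_patterns = n_pat))
    },
    density_sweep = as.data.frame(sweep_density_rf(n_patterns = n_pat,
                                                   params = sp)),
    refresh_sweep = as.data.frame(sweep_refresh_rf(n_trials = n_tr,
                                                   params = sp)),
    population_tuning = as.data.frame(
      population_tuning(n_patterns = n_pat, params = sp)),
    correlation_disparity = as.data.frame(
      correlation_disparity_experiment(n_trials = n_tr,
                                       target = cfg$target_accuracy,
                                       params = sp)),
    correlation_refresh = as.data.frame(
      correlation_refresh_experiment(n_trials = n_tr,
                                     target = cfg$target_accuracy,
                                     kernel = if (is.null(kern))
                                       temporal_kernel() else kern,
                                     params = sp)),
    dot_size = as.data.frame(
      dot_size_experiment(n_trials = n_tr, target = cfg$target_accuracy,
                          kernel = if (is.null(kern))
                            temporal_kernel() else kern,
                          params = sp)),
    alternation = as.data.frame(
      alternation_experiment(n_trials = n_tr, exponent = cfg$exponent,
                             kernel_kind = if (cfg$kernel == "none")
                               "biphasic" else cfg$kernel,
                             target = cfg$target_accuracy,
                             disparity_deg = cfg$disparity_deg)),
    stop("unhandled experiment: ", cfg$experiment))
  csv <- file.path(cfg$out_dir, paste0(cfg$experiment, ".csv"))
  utils::write.csv(res, csv, row.names = FALSE)
  manifest <- list(config = unclass(cfg)[names(config_fields())],
                   seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("stereobem")),
                   r_version = R.version.string,
                   wall_clock_s = as.numeric(difftime(Sys.time(), t0,
                                                      units = "secs")))
  mj <- file.path(cfg$out_dir, paste0(cfg$experiment, "_manifest.json"))
  jsonlite::write_json(manifest, mj, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  attr(res, "paths") <- c(csv = csv, manifest = mj)
  invisible(res)
}
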