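# Run configuration: a nested list covering every stage of the pipeline,
# validated strictly (unknown keys are errors), written/read as YAML.

#' Default run configuration
#'
#' The default describes the wild-type study conditions: a 15 x 30
#' periodic box (cell-diameter units) holding 450 cells, five stripe
#' positions spaced 3 diameters apart, an early negative template with
#' notches at stripes 1/3/5, late inhibitory halos around stripes 1/5,
#' and a 30-tau simulation through the early-to-late transition.
#'
#' @param n_cells,box_height optionally scale the tissue along the
#'   stripe direction (the stripe layout fixes the box width); `n_cells`
#'   must equal `box_width * box_height` times the unit cell density.
#' @return A named nested list (sections `lattice`, `coupling`, `model`,
#'   `gradient`, `simulation`, `profile`).
#' @export
default_config <- function(n_cells = 450L, box_height = 30) {
  list(
    lattice = list(n_cells = as.integer(n_cells), box_width = 15,
                   box_height = box_height, disorder = 0.3,
                   n_lloyd = 20L),
    coupling = list(signaling_range = 1, strength = 2,
                    cutoff_factor = 3, normalized = FALSE),
    model = list(tau = 1, f_threshold = 0.2, f_steepness = 0.1,
                 noise_sigma = 0.02, d_mid = 0.5, d_steepness = 0.1,
                 fate_threshold = 0.5),
    gradient = list(
      early = list(plateau = 1, notch_centers = c(1.5, 7.5, 13.5),
                   notch_width = 1, notch_depth = 1),
      late = list(centers = c(1.5, 13.5), amplitude = 0.5, width = 1.2,
                  core_width = 0.5),
      t_start = 5, t_end = 15),
    simulation = list(t_end = 30, dt = 0.02, record_every = 25L,
                      seed = 1L),
    profile = list(bin_width = 2, range = 20, threshold = 0.2,
                   statistic = "sum_minus_threshold"))
}

#' Validate a run configuration
#'
#' Checks the section/key structure against [default_config()] (unknown
#' keys are errors, not warnings), fills missing keys with defaults, and
#' enforces the numeric preconditions of every pipeline stage.
#'
#' @param config a nested configuration list.
#' @return The completed configuration, invisibly classed as
#'   `run_config`.
#' @export
validate_config <- function(config) {
  ref <- default_config()
  check_keys <- function(cfg, ref, path) {
    unknown <- setdiff(names(cfg), names(ref))
    if (length(unknown))
      stop("unknown configuration key: ",
           paste0(path, unknown, collapse = ", "))
  }
  check_keys(config, ref, "")
  for (sec in names(ref)) {
    if (is.null(config[[sec]])) {
      config[[sec]] <- ref[[sec]]
      next
    }
    check_keys(config[[sec]], ref[[sec]], paste0(sec, "$"))
    if (sec == "gradient") {
      for (sub in c("early", "late")) {
        if (!is.null(config$gradient[[sub]]))
          check_keys(config$gradient[[sub]], ref$gradient[[sub]],
                     paste0("gradient$", sub, "$"))
      }
    }
    for (key in names(ref[[sec]])) {
      if (is.null(config[[sec]][[key]]))
        config[[sec]][[key]] <- ref[[sec]][[key]]
      else if (is.list(ref[[sec]][[key]])) {
        for (k2 in names(ref[[sec]][[key]]))
          if (is.null(config[[sec]][[key]][[k2]]))
            config[[sec]][[key]][[k2]] <- ref[[sec]][[key]][[k2]]
      }
    }
  }
  lc <- config$lattice
  if (lc$n_cells < 1) stop("lattice$n_cells must be >= 1")
  if (lc$box_width <= 0 || lc$box_height <= 0)
    stop("lattice box dimensions must be positive")
  if (config$coupling$signaling_range <= 0)
    stop("coupling$signaling_range must be positive")
  if (config$coupling$strength < 0)
    stop("coupling$strength must be nonnegative")
  if (config$simulation$dt <= 0 ||
      config$simulation$dt > config$model$tau / 10)
    stop("simulation$dt must be positive and at most tau / 10")
  if (config$gradient$t_start > config$gradient$t_end)
    stop("gradient$t_start must be <= gradient$t_end")
  if (config$profile$bin_width <= 0)
    stop("profile$bin_width must be positive")
  if (!config$profile$statistic %in%
      c("sum_minus_threshold", "mean_intensity"))
    stop("profile$statistic must be 'sum_minus_threshold' or",
         " 'mean_intensity'")
  class(config) <- c("run_config", "list")
  invisible(config)
}

#' Regime presets for the genetic-perturbation phenotypes
#'
#' Pure transformations of a base configuration mirroring the
#' perturbations studied in the bristle-patterning system:
#' \describe{
#'   \item{wild_type}{the base configuration, unchanged.}
#'   \item{no_template}{flattens the early-profile notches
#'     (`notch_depth = 0`): loss of the early, proneural-independent
#'     negative template, as when early Notch targets are removed.}
#'   \item{reduced_late_inhibition}{scales the state-dependent cell-cell
#'     inhibition down by `late_factor` (default 0.6): weakened
#'     proneural-dependent mutual inhibition, as when the late-onset
#'     repressors are deleted.}
#'   \item{no_inhibition}{sets the coupling strength to 0 and removes
#'     the late profile: complete loss of Notch-mediated inhibition
#'     after the template phase.}
#' }
#'
#' @param name one of `"wild_type"`, `"no_template"`,
#'   `"reduced_late_inhibition"`, `"no_inhibition"`.
#' @param base base configuration (default [default_config()]).
#' @param late_factor scaling applied by `reduced_late_inhibition`.
#' @return A validated full run configuration.
#' @export
make_regime_config <- function(name, base = default_config(),
                               late_factor = 0.6) {
  valid <- c("wild_type", "no_template", "reduced_late_inhibition",
             "no_inhibition")
  if (!name %in% valid)
    stop("unknown regime '", name, "'; valid regimes: ",
         paste(valid, collapse = ", "))
  cfg <- base
  if (name == "no_template") {
    cfg$gradient$early$notch_depth <- 0
  } else if (name == "reduced_late_inhibition") {
    cfg$coupling$strength <- cfg$coupling$strength * late_factor
  } else if (name == "no_inhibition") {
    cfg$coupling$strength <- 0
    cfg$gradient$late$amplitude <- 0
  }
  validate_config(cfg)
}

#' Read a run configuration from YAML
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' Write a run configuration to YAML
#' @param config a configuration list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
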