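# Pipeline configuration: one nested structure that collects every tunable
# of the acquisition, recovery and deconvolution stages. Defaults follow the
# instrument operating point: 0.532 um illumination, 1.67 um detector
# pixels, a 6 x 6 sub-pixel grid, six heights 20 um apart, and beta = 0.001
# for the deconvolution.

config_defaults <- function() {
  list(
    optical = list(
      wavelength = 0.532,
      pixel_pitch = 1.67,
      upsample_factor = 6L,
      z_sample_to_sensor = 721,
      z_source_to_sample = 80000,
      refractive_index = 1.0
    ),
    acquisition = list(
      n_heights = 6L,
      z_step = 20,
      noise_sigma = 0,
      scene = list(
        type = "beads",          # "beads" or "bars"
        n_beads = 6L,            # (not `n`: a bare n is boolean in YAML 1.1)
        diameter = 1.0,
        z_planes = c(700, 760),
        bar_widths = c(3, 2),
        shape = c(192L, 192L)
      )
    ),
    psr = list(deblur = FALSE, reg = 1e-3),
    recovery = list(tol = 1e-4, max_iter = 50L, init = "zero",
                    refine_z = FALSE),
    deconvolution = list(method = "gold", beta = 0.001, iters = 20L,
                         mode = "amplitude", background = "mean",
                         z_start = 670, z_stop = 790, z_step = 10),
    seed = 42L
  )
}

# deep-merge user values over defaults, erroring on unknown keys
merge_config <- function(defaults, user, path = character()) {
  for (key in names(user)) {
    here <- paste(c(path, key), collapse = "$")
    if (!key %in% names(defaults))
      stop(sprintf("unknown configuration key `%s`", here), call. = FALSE)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        stop(sprintf("`%s` must be a mapping", here), call. = FALSE)
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

validate_config <- function(cfg) {
  o <- cfg$optical
  if (o$wavelength <= 0) stop("optical$wavelength must be > 0", call. = FALSE)
  if (o$pixel_pitch <= 0) stop("optical$pixel_pitch must be > 0",
                               call. = FALSE)
  cfg$optical$upsample_factor <- as.integer(o$upsample_factor)
  if (is.na(cfg$optical$upsample_factor) ||
      cfg$optical$upsample_factor < 1L)
    stop("optical$upsample_factor must be an integer >= 1", call. = FALSE)
  a <- cfg$acquisition
  cfg$acquisition$n_heights <- as.integer(a$n_heights)
  if (cfg$acquisition$n_heights < 2L)
    stop("acquisition$n_heights must be >= 2", call. = FALSE)
  if (a$z_step < 2)
    stop("acquisition$z_step below 2 um makes phase recovery unreliable",
         call. = FALSE)
  if (!cfg$acquisition$scene$type %in% c("beads", "bars"))
    stop("acquisition$scene$type must be \"beads\" or \"bars\"",
         call. = FALSE)
  cfg$acquisition$scene$shape <- as.integer(cfg$acquisition$scene$shape)
  if (cfg$recovery$tol <= 0) stop("recovery$tol must be > 0", call. = FALSE)
  cfg$recovery$max_iter <- as.integer(cfg$recovery$max_iter)
  if (!cfg$recovery$init %in% c("zero", "random"))
    stop("recovery$init must be \"zero\" or \"random\"", call. = FALSE)
  d <- cfg$deconvolution
  if (!d$method %in% c("gold", "wiener"))
    stop("deconvolution$method must be \"gold\" or \"wiener\"", call. = FALSE)
  if (d$beta < 0) stop("deconvolution$beta must be >= 0", call. = FALSE)
  cfg$deconvolution$iters <- as.integer(d$iters)
  if (!d$mode %in% c("amplitude", "complex"))
    stop("deconvolution$mode must be \"amplitude\" or \"complex\"",
         call. = FALSE)
  if (!d$background %in% c("mean", "none"))
    stop("deconvolution$background must be \"mean\" or \"none\"",
         call. = FALSE)
  if (d$z_stop < d$z_start || d$z_step <= 0)
    stop("deconvolution z grid must have z_stop >= z_start, z_step > 0",
         call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Build a pipeline configuration
#'
#' Returns the default configuration with any supplied overrides deep-merged
#' in. Unknown keys are rejected with their location.
#'
#' @param ... Named top-level blocks to override, e.g.
#'   \code{pipeline_config(deconvolution = list(method = "wiener"))}.
#' @return A validated \code{pipeline_config}.
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  validate_config(merge_config(config_defaults(), user))
}

#' Load a pipeline configuration from YAML
#'
#' An empty file yields the full default configuration; supplied keys
#' override defaults; unknown keys raise an error naming the offending key.
#'
#' @param path YAML file path.
#' @return A validated \code{pipeline_config}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  validate_config(merge_config(config_defaults(), user))
}

#' Save a pipeline configuration to YAML
#'
#' Writes the full configuration; \code{load_config} of the result
#' reproduces it exactly.
#'
#' @param config A \code{pipeline_config}.
#' @param path Output YAML path.
#' @return The path, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Extract the optical configuration from a pipeline configuration
#' @param config A \code{pipeline_config}.
#' @return An \code{optical_config}.
#' @export
as_optical_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  do.call(optical_config, config$optical)
}
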