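# Configuration templates: the full parameter set for the pipeline
# (enabled flags + parameters per step), excluding free metadata text
# and MV labels.  Templates round-trip losslessly through XML (see
# save_config()/load_config()).

#' Create a pipeline configuration template
#'
#' Returns a configuration with every step disabled and conventional
#' parameter defaults; enable and adjust fields before passing it to
#' [run_pipeline()].  See [interpret_template()] for the shipped
#' canonical-format configuration.
#'
#' @return An object of class `mrs_config`: a named list with one entry
#'   per pipeline step (`set_reference`, `apodize`, `water_filter`,
#'   `baseline`, `change_points`, `set_to_zero`, `normalization`,
#'   `alignment`, `output_range`) plus `snr_noise`, the noise region
#'   used for per-voxel SNR reporting.
#' @export
config_template <- function() {
  structure(
    list(
      set_reference = list(enabled = FALSE, reference = 4.75),
      apodize = list(enabled = FALSE, shape = "Lorentzian", linewidth = 1),
      water_filter = list(enabled = FALSE, n_lorentzians = 10L,
                          regions = list(ppm_range(5.1, 4.3))),
      baseline = list(enabled = FALSE, regions = list()),
      change_points = list(enabled = FALSE, target_points = 512L,
                           range = ppm_range(7.1, -2.7)),
      set_to_zero = list(enabled = FALSE, intervals = list()),
      normalization = list(enabled = FALSE),
      alignment = list(enabled = FALSE, peaks = numeric(),
                       noise = NULL, brain_1p5T_preset = FALSE),
      output_range = list(enabled = FALSE, range = ppm_range(7.1, -2.7)),
      snr_noise = NULL
    ),
    class = "mrs_config"
  )
}

#' The canonical 512-point harmonization template
#'
#' Configuration reproducing the canonical pattern-recognition format:
#' 512 points spanning 7.1 to -2.7 ppm (first point at 7.1 ppm), with
#' unit-length normalization and SNR-guided alignment enabled.  The
#' alignment peak list holds the major proton-brain singlets (choline
#' 3.21, creatine 3.03, N-acetylaspartate 2.01 ppm) and the noise
#' region sits in the signal-free upfield tail.  Because normalization
#' (Step VII) always precedes the output crop (Step IX), the template
#' zeroes the spectral tails outside the canonical window (Step VI)
#' first, so the exported 512-point vector itself has unit norm.
#'
#' @return An `mrs_config` object.
#' @export
interpret_template <- function() {
  cfg <- config_template()
  cfg$change_points <- list(enabled = TRUE, target_points = 512L,
                            range = ppm_range(7.1, -2.7))
  cfg$set_to_zero <- list(enabled = TRUE, intervals = list(
    ppm_range(1000, 7.1001), ppm_range(-2.7001, -1000)
  ))
  cfg$normalization <- list(enabled = TRUE)
  cfg$alignment <- list(enabled = TRUE, peaks = c(3.21, 3.03, 2.01),
                        noise = ppm_range(-0.7, -2.7),
                        brain_1p5T_preset = FALSE)
  cfg$output_range <- list(enabled = TRUE, range = ppm_range(7.1, -2.7))
  cfg$snr_noise <- ppm_range(-0.7, -2.7)
  cfg
}

is_config <- function(x) inherits(x, "mrs_config")

#' Expand a configuration into the ordered step records it implies
#'
#' @param config An `mrs_config` object.
#' @return List of [step_record()] objects for the enabled steps, in
#'   fixed pipeline order (lower step numbers first) regardless of how
#'   the configuration was authored.
#' @export
config_to_steps <- function(config) {
  if (!is_config(config)) {
    mrs_parameter_error("'config' must be an mrs_config object")
  }
  steps <- list()
  add <- function(steps, id, params) c(steps, list(step_record(id, params)))
  if (isTRUE(config$set_reference$enabled)) {
    steps <- add(steps, "SetReference",
                 list(reference = config$set_reference$reference))
  }
  if (isTRUE(config$apodize$enabled)) {
    steps <- add(steps, "Apodize",
                 list(shape = config$apodize$shape,
                      linewidth = config$apodize$linewidth))
  }
  if (isTRUE(config$water_filter$enabled)) {
    steps <- add(steps, "WaterFiltering",
                 list(n_lorentzians = as.integer(config$water_filter$n_lorentzians),
                      regions = config$water_filter$regions))
  }
  if (isTRUE(config$baseline$enabled)) {
    steps <- add(steps, "BaselineCorrection",
                 list(regions = config$baseline$regions))
  }
  if (isTRUE(config$change_points$enabled)) {
    steps <- add(steps, "ChangePoints",
                 list(target_points = as.integer(config$change_points$target_points),
                      range = config$change_points$range))
  }
  if (isTRUE(config$set_to_zero$enabled)) {
    steps <- add(steps, "SetToZero",
                 list(intervals = config$set_to_zero$intervals))
  }
  if (isTRUE(config$normalization$enabled)) {
    steps <- add(steps, "Normalization", list(type = "l2"))
  }
  if (isTRUE(config$alignment$enabled)) {
    noise <- config$alignment$noise
    if (is.null(noise)) {
      mrs_validation_error("alignment is enabled but no noise region is set")
    }
    steps <- add(steps, "AlignmentCorrection",
                 list(peaks = as.numeric(config$alignment$peaks),
                      noise = noise,
                      brain_1p5T_preset = isTRUE(config$alignment$brain_1p5T_preset)))
  }
  if (isTRUE(config$output_range$enabled)) {
    steps <- add(steps, "OutputRange", list(range = config$output_range$range))
  }
  steps
}
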