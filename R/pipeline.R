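# Pipeline driver: executes the enabled steps in fixed order on a
# single voxel or uniformly on every voxel of a grid, inserting
# time/frequency domain conversions automatically, and assembles the
# resulting dataset with its complete provenance record.

# Operation counter: one tick per operator application, so tests can
# assert that total work scales linearly with voxel count without
# relying on wall-clock timing.
.mrs_counters <- new.env(parent = emptyenv())
.mrs_counters$ops <- 0L

#' Reset / read the operator application counter
#'
#' Every preprocessing step applied by [replay_steps()] (and therefore
#' by [run_pipeline()]) increments an internal counter.  Useful for
#' asserting work scaling (voxels are processed sequentially, so total
#' operator applications grow linearly with voxel count).
#'
#' @return `op_count()` returns the current count; `reset_op_count()`
#'   resets it to zero invisibly.
#' @export
op_count <- function() .mrs_counters$ops

#' @rdname op_count
#' @export
reset_op_count <- function() {
  .mrs_counters$ops <- 0L
  invisible(NULL)
}

# Apply one recorded step to a frequency-domain spectrum, converting to
# the time domain where the operator demands it (apodization and HLSVD
# filtering act on the FID; everything else on the spectrum).
apply_step <- function(spec, rec) {
  stopifnot(is_step_record(rec))
  .mrs_counters$ops <- .mrs_counters$ops + 1L
  p <- rec$parameters
  switch(rec$step_id,
    SetReference = set_reference(spec, p$reference),
    Apodize = to_frequency_domain(
      apodize(to_time_domain(spec), p$shape, p$linewidth)
    ),
    WaterFiltering = to_frequency_domain(
      hlsvd_filter(to_time_domain(spec), p$n_lorentzians, p$regions)
    ),
    BaselineCorrection = baseline_correct(spec, p$regions),
    ChangePoints = change_points_in_range(spec, p$target_points, p$range),
    SetToZero = set_to_zero(spec, p$intervals),
    Normalization = l2_normalize(spec),
    AlignmentCorrection = align(
      spec,
      alignment_spec(p$peaks, p$noise, p$brain_1p5T_preset %||% FALSE)
    ),
    OutputRange = output_range(spec, p$range),
    mrs_validation_error(sprintf("unknown step '%s'", rec$step_id))
  )
}

#' Replay a sequence of recorded preprocessing steps
#'
#' Applies step records (e.g. taken from a dataset's provenance) to a
#' raw input in order.  Because every operator is a deterministic
#' function of its recorded parameters, replaying the provenance of a
#' pipeline run on the same raw input reproduces its output exactly.
#'
#' @param input An [time_signal()] (transformed to the frequency domain
#'   first) or [spectrum()] object.
#' @param steps List of [step_record()] objects in application order.
#' @return The processed [spectrum()], provenance included.
#' @export
replay_steps <- function(input, steps) {
  spec <- if (inherits(input, "mrs_fid")) to_frequency_domain(input) else input
  if (!inherits(spec, "mrs_spectrum")) {
    mrs_parameter_error("'input' must be an mrs_fid or mrs_spectrum object")
  }
  for (rec in steps) spec <- apply_step(spec, rec)
  spec
}

#' Run the preprocessing pipeline and assemble a dataset
#'
#' Executes the steps enabled in `config` in fixed order (lower step
#' numbers first) with the required time/frequency-domain conversions
#' inserted automatically.  A grid input is processed voxel by voxel
#' with the identical step sequence.  When
#' `info$include_snr` is set, each voxel's SNR is computed over the
#' whole processed spectrum against the `config$snr_noise` region and
#' stored with the voxel.
#'
#' @param input An [time_signal()] or [spectrum()] for a single voxel,
#'   or an [grid_record()] of raw voxels for multi-voxel data.
#' @param config An `mrs_config` object (see [config_template()]).
#' @param info An [additional_info()] object; for single-voxel data its
#'   `label` becomes the voxel label.
#' @return An [mrs_dataset()] pairing the provenance record with the
#'   processed payload.
#' @export
run_pipeline <- function(input, config, info) {
  if (!is_additional_info(info)) {
    mrs_validation_error("'info' must be an additional_info object")
  }
  steps <- config_to_steps(config)
  snr_noise <- config$snr_noise
  if (info$include_snr && is.null(snr_noise)) {
    mrs_validation_error(
      "include_snr is set but the configuration has no snr_noise region"
    )
  }
  attach_snr <- function(spec) {
    if (info$include_snr) compute_snr(spec, noise_region(snr_noise)) else NULL
  }

  if (inherits(input, "mrs_grid")) {
    voxels <- vector("list", length(input$voxels))
    for (i in seq_along(input$voxels)) {
      vx <- input$voxels[[i]]
      out <- tryCatch(
        replay_steps(vx$spectrum, steps),
        mrs_error = function(e) {
          pos <- vx$position %||% c(NA_integer_, NA_integer_, NA_integer_)
          mrs_error(
            sprintf("voxel [row %s, col %s]: %s", pos[2], pos[1],
                    conditionMessage(e)),
            class(e)[1]
          )
        }
      )
      voxels[[i]] <- voxel_record(out, label = vx$label,
                                  snr = attach_snr(out))
    }
    payload <- grid_record(voxels, input$rows, input$cols)
    done <- provenance_steps(payload$voxels[[1]]$spectrum)
  } else {
    out <- replay_steps(input, steps)
    payload <- voxel_record(out, label = info$label, snr = attach_snr(out))
    done <- provenance_steps(out)
  }
  mrs_dataset(preprocessing_record(done, info), payload)
}
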