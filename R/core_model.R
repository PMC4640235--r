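#' Acquisition parameters for an MRS signal
#'
#' Bundles the minimal acquisition context required to construct a
#' chemical-shift (ppm) axis for a free-induction decay (FID):
#' transmitter frequency, sweep width, number of complex points and the
#' ppm value assigned to the carrier frequency.
#'
#' @param transmitter_frequency Transmitter (carrier) frequency in MHz.
#' @param sweep_width Spectral width in Hz.
#' @param num_points Number of complex data points (>= 2).
#' @param reference_ppm ppm value assigned to the carrier, i.e. to the
#'   centre of the spectral window.  Defaults to 4.7 (water in proton
#'   spectra at body temperature is commonly referenced near 4.7 ppm).
#' @param nucleus Free-text nucleus label, e.g. `"1H"`.
#'
#' @return An object of class `mrs_params`.
#' @export
#' @examples
#' acquisition_params(63.86, 1000, 512, reference_ppm = 4.7)
acquisition_params <- function(transmitter_frequency, sweep_width, num_points,
                               reference_ppm = 4.7, nucleus = "1H") {
  if (!is.numeric(transmitter_frequency) || length(transmitter_frequency) != 1 ||
      !is.finite(transmitter_frequency) || transmitter_frequency <= 0) {
    mrs_parameter_error("'transmitter_frequency' must be a single positive number (MHz)")
  }
  if (!is.numeric(sweep_width) || length(sweep_width) != 1 ||
      !is.finite(sweep_width) || sweep_width <= 0) {
    mrs_parameter_error("'sweep_width' must be a single positive number (Hz)")
  }
  if (!is.numeric(num_points) || length(num_points) != 1 ||
      num_points != round(num_points) || num_points < 2) {
    mrs_parameter_error("'num_points' must be an integer >= 2")
  }
  if (!is.numeric(reference_ppm) || length(reference_ppm) != 1 ||
      !is.finite(reference_ppm)) {
    mrs_parameter_error("'reference_ppm' must be a single finite number")
  }
  structure(
    list(
      transmitter_frequency = as.numeric(transmitter_frequency),
      sweep_width = as.numeric(sweep_width),
      num_points = as.integer(num_points),
      reference_ppm = as.numeric(reference_ppm),
      nucleus = as.character(nucleus)
    ),
    class = "mrs_params"
  )
}

#' @export
print.mrs_params <- function(x, ...) {
  cat(sprintf(
    "MRS acquisition: %s, %.6g MHz, sweep %.6g Hz, %d points, ref %.4g ppm\n",
    x$nucleus, x$transmitter_frequency, x$sweep_width, x$num_points,
    x$reference_ppm
  ))
  invisible(x)
}

is_params <- function(x) inherits(x, "mrs_params")

#' Dwell time of an acquisition
#'
#' @param params An [acquisition_params()] object.
#' @return Sampling interval in seconds (`1 / sweep_width`).
#' @export
dwell_time <- function(params) {
  stopifnot(is_params(params))
  1 / params$sweep_width
}

# 0-based index of the carrier bin; ppm axis value there equals
# reference_ppm.  floor(n/2) matches the conventional FFT centre bin.
carrier_index0 <- function(n) n %/% 2L

#' Construct the ppm axis implied by acquisition parameters
#'
#' The axis is strictly decreasing (high ppm on the left, the standard
#' MRS plotting order).  Index `k` (0-based) maps to
#' `reference_ppm + (floor(n/2) - k) * sweep_width / (transmitter_frequency * n)`,
#' so the centre bin carries exactly `reference_ppm`.
#'
#' @param params An [acquisition_params()] object.
#' @return Numeric vector of `num_points` ppm coordinates, strictly
#'   decreasing.
#' @export
#' @examples
#' build_ppm_axis(acquisition_params(1, 4, 4, reference_ppm = 0))
build_ppm_axis <- function(params) {
  if (!is_params(params)) {
    mrs_parameter_error("'params' must be an acquisition_params object")
  }
  n <- params$num_points
  step <- params$sweep_width / (params$transmitter_frequency * n)
  params$reference_ppm + (carrier_index0(n) - seq.int(0L, n - 1L)) * step
}

ppm_step <- function(params) {
  params$sweep_width / (params$transmitter_frequency * params$num_points)
}

# Signed baseband frequency (Hz) of a resonance at `ppm`, and back.
# Positive offsets sit on the high-ppm (left) side of the axis.
ppm_to_hz <- function(ppm, params) (ppm - params$reference_ppm) * params$transmitter_frequency
hz_to_ppm <- function(hz, params) params$reference_ppm + hz / params$transmitter_frequency

#' Time-domain MRS signal (free-induction decay)
#'
#' @param samples Complex vector of FID samples; length must equal
#'   `params$num_points`.
#' @param params An [acquisition_params()] object.
#' @return An object of class `mrs_fid` with fields `samples` and
#'   `params`.
#' @export
time_signal <- function(samples, params) {
  if (!is_params(params)) {
    mrs_parameter_error("'params' must be an acquisition_params object")
  }
  if (!is.numeric(samples) && !is.complex(samples)) {
    mrs_parameter_error("'samples' must be numeric or complex")
  }
  if (length(samples) != params$num_points) {
    mrs_parameter_error(sprintf(
      "length(samples) is %d but params$num_points is %d",
      length(samples), params$num_points
    ))
  }
  structure(
    list(samples = as.complex(samples), params = params),
    class = "mrs_fid",
    steps = list()
  )
}

#' @export
print.mrs_fid <- function(x, ...) {
  cat(sprintf(
    "MRS FID: %d complex points, dwell %.3g s, %d recorded step(s)\n",
    length(x$samples), dwell_time(x$params), length(attr(x, "steps"))
  ))
  invisible(x)
}

#' Frequency-domain MRS spectrum
#'
#' A complex spectral vector together with its ppm axis.  The axis is
#' always the uniform grid implied by `params` (see [build_ppm_axis()]),
#' which keeps the compact `(ppm_first, ppm_step, n)` serialization
#' exact.
#'
#' @param intensities Complex vector of spectral intensities.
#' @param params An [acquisition_params()] object with `num_points`
#'   equal to `length(intensities)`.
#' @return An object of class `mrs_spectrum` with fields `intensities`,
#'   `axis` and `params`.
#' @export
spectrum <- function(intensities, params) {
  if (!is_params(params)) {
    mrs_parameter_error("'params' must be an acquisition_params object")
  }
  if (!is.numeric(intensities) && !is.complex(intensities)) {
    mrs_parameter_error("'intensities' must be numeric or complex")
  }
  if (length(intensities) != params$num_points) {
    mrs_parameter_error(sprintf(
      "length(intensities) is %d but params$num_points is %d",
      length(intensities), params$num_points
    ))
  }
  structure(
    list(
      intensities = as.complex(intensities),
      axis = build_ppm_axis(params),
      params = params
    ),
    class = "mrs_spectrum",
    steps = list()
  )
}

#' @export
print.mrs_spectrum <- function(x, ...) {
  cat(sprintf(
    "MRS spectrum: %d points, %.4g to %.4g ppm, %d recorded step(s)\n",
    length(x$intensities), x$axis[1], x$axis[length(x$axis)],
    length(attr(x, "steps"))
  ))
  invisible(x)
}

#' Closed ppm interval
#'
#' Ranges are closed: a point at coordinate `p` belongs to the range iff
#' `lower <= p <= upper`.
#'
#' @param upper Upper bound in ppm.
#' @param lower Lower bound in ppm; must be strictly below `upper`.
#' @return An object of class `mrs_ppm_range`.
#' @export
#' @examples
#' ppm_range(5.2, 4.2) # residual-water neighbourhood in proton spectra
ppm_range <- function(upper, lower) {
  if (!is.numeric(upper) || !is.numeric(lower) ||
      length(upper) != 1 || length(lower) != 1 ||
      !is.finite(upper) || !is.finite(lower)) {
    mrs_parameter_error("'upper' and 'lower' must be single finite numbers")
  }
  if (upper <= lower) {
    mrs_parameter_error("'upper' must be strictly greater than 'lower'")
  }
  structure(list(upper = as.numeric(upper), lower = as.numeric(lower)),
            class = "mrs_ppm_range")
}

is_ppm_range <- function(x) inherits(x, "mrs_ppm_range")

# Logical mask of axis coordinates inside a closed range.
in_range <- function(axis, range) {
  axis >= range$lower & axis <= range$upper
}

#' Noise region for SNR estimation
#'
#' Designates the stretch of the spectrum treated as signal-free noise
#' when evaluating SNR.  Must contain at least two spectral points when
#' resolved against an axis.
#'
#' @param range An [ppm_range()] object.
#' @return An object of class `mrs_noise_region`.
#' @export
noise_region <- function(range) {
  if (!is_ppm_range(range)) {
    mrs_parameter_error("'range' must be a ppm_range object")
  }
  structure(list(range = range), class = "mrs_noise_region")
}

is_noise_region <- function(x) inherits(x, "mrs_noise_region")

## ---- provenance ------------------------------------------------------

# Fixed execution/serialization order of the preprocessing steps.
STEP_ORDER <- c(
  SetReference = 1L,
  Apodize = 2L,
  WaterFiltering = 3L,
  BaselineCorrection = 4L,
  ChangePoints = 5L,
  SetToZero = 6L,
  Normalization = 7L,
  AlignmentCorrection = 8L,
  OutputRange = 9L
)

#' Provenance record of a single preprocessing step
#'
#' @param step_id One of `names(mrsxml:::STEP_ORDER)`:
#'   `"SetReference"`, `"Apodize"`, `"WaterFiltering"`,
#'   `"BaselineCorrection"`, `"ChangePoints"`, `"SetToZero"`,
#'   `"Normalization"`, `"AlignmentCorrection"`, `"OutputRange"`.
#' @param parameters Named list holding exactly the inputs given to the
#'   step.
#' @return An object of class `mrs_step`.
#' @export
step_record <- function(step_id, parameters = list()) {
  if (!is.character(step_id) || length(step_id) != 1 ||
      !step_id %in% names(STEP_ORDER)) {
    mrs_parameter_error(sprintf(
      "unknown step_id '%s'; must be one of: %s",
      as.character(step_id)[1], paste(names(STEP_ORDER), collapse = ", ")
    ))
  }
  structure(list(step_id = step_id, parameters = parameters),
            class = "mrs_step")
}

is_step_record <- function(x) inherits(x, "mrs_step")

# Attach one provenance entry to a signal or spectrum.
append_step <- function(x, step_id, parameters = list()) {
  attr(x, "steps") <- c(attr(x, "steps"), list(step_record(step_id, parameters)))
  x
}

#' Retrieve the provenance steps recorded on an object
#'
#' @param x An `mrs_fid`, `mrs_spectrum` or `mrs_dataset` object.
#' @return List of [step_record()] objects, in application order.
#' @export
provenance_steps <- function(x) {
  if (inherits(x, "mrs_dataset")) return(x$preprocessing$steps)
  attr(x, "steps") %||% list()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Carry provenance (and any other mrsxml attributes) across a transform.
carry_steps <- function(to, from) {
  attr(to, "steps") <- attr(from, "steps") %||% list()
  to
}

#' Additional information block (user, place, labels, keywords)
#'
#' Name and place are compulsory: they guarantee minimum traceability of
#' who performed the preprocessing and where.  The date is assigned
#' automatically at export time.
#'
#' @param name User's name; non-empty.
#' @param place Place (site/institution); non-empty.
#' @param label Dataset label; defaults to `"***"`.
#' @param keywords Character vector of keywords, each at most 45
#'   characters.
#' @param include_snr Logical; record per-voxel SNR in the output?
#' @param meta_data Free observation-notebook text, stored verbatim.
#' @param date Optional ISO-8601 date string; normally left `NULL` and
#'   filled in by [export_dataset()].
#' @return An object of class `mrs_additional_info`.
#' @export
additional_info <- function(name, place, label = "***", keywords = character(),
                            include_snr = FALSE, meta_data = "", date = NULL) {
  if (!is.character(name) || length(name) != 1 || !nzchar(trimws(name))) {
    mrs_validation_error("user's Name is compulsory and must be non-empty")
  }
  if (!is.character(place) || length(place) != 1 || !nzchar(trimws(place))) {
    mrs_validation_error("Place is compulsory and must be non-empty")
  }
  keywords <- as.character(keywords)
  too_long <- nchar(keywords) > 45L
  if (any(too_long)) {
    mrs_validation_error(sprintf(
      "keyword length exceeds the 45-character maximum: '%s'",
      keywords[too_long][1]
    ))
  }
  structure(
    list(
      name = name, place = place, date = date,
      label = as.character(label), keywords = keywords,
      include_snr = isTRUE(include_snr), meta_data = as.character(meta_data)
    ),
    class = "mrs_additional_info"
  )
}

is_additional_info <- function(x) inherits(x, "mrs_additional_info")

#' Ordered preprocessing provenance
#'
#' @param steps List of [step_record()] objects; must appear in
#'   nondecreasing step order (lower roman numbers first).
#' @param additional_info An [additional_info()] object (always
#'   required).
#' @return An object of class `mrs_preprocessing`.
#' @export
preprocessing_record <- function(steps = list(), additional_info) {
  if (!is_additional_info(additional_info)) {
    mrs_validation_error("'additional_info' is always required")
  }
  if (!all(vapply(steps, is_step_record, logical(1)))) {
    mrs_parameter_error("'steps' must be a list of step_record objects")
  }
  ord <- vapply(steps, function(s) STEP_ORDER[[s$step_id]], integer(1))
  if (length(ord) > 1 && any(diff(ord) < 0)) {
    mrs_validation_error(
      "preprocessing steps must appear in nondecreasing pipeline order"
    )
  }
  structure(list(steps = steps, additional_info = additional_info),
            class = "mrs_preprocessing")
}

## ---- SV / MV containers ---------------------------------------------

#' Single labelled voxel
#'
#' @param spectrum An [spectrum()] object.
#' @param label Voxel label; defaults to `"***"`.
#' @param snr Optional `mrs_snr` result (see [compute_snr()]).
#' @param position Optional integer triple `(x, y, z)` of 1-based grid
#'   indices; `x` is the column and `y` the row.  Inside a grid `z` is
#'   always 1 (single-slice acquisitions).
#' @return An object of class `mrs_voxel`.
#' @export
voxel_record <- function(spectrum, label = "***", snr = NULL, position = NULL) {
  if (!inherits(spectrum, "mrs_spectrum")) {
    mrs_parameter_error("'spectrum' must be an mrs_spectrum object")
  }
  if (!is.null(position)) {
    if (length(position) != 3 || any(position != round(position)) ||
        any(position < 1)) {
      mrs_parameter_error("'position' must be three 1-based integer indices")
    }
    position <- as.integer(position)
  }
  if (!is.null(snr) && !inherits(snr, "mrs_snr")) {
    mrs_parameter_error("'snr' must be an mrs_snr object or NULL")
  }
  structure(
    list(spectrum = spectrum, label = as.character(label), snr = snr,
         position = position),
    class = "mrs_voxel"
  )
}

#' Multi-voxel grid
#'
#' Voxels are arranged in matrix notation: the top-left voxel is at
#' `[1, 1]` and the bottom-right at `[rows, cols]`.  The stored
#' position attributes are axis-named, so column maps to `Xaxis` and
#' row to `Yaxis`; `Zaxis` is always 1.
#'
#' @param voxels List of [voxel_record()] objects, row-major (all of
#'   row 1 first), length `rows * cols`.
#' @param rows,cols Grid dimensions.
#' @return An object of class `mrs_grid`.
#' @export
grid_record <- function(voxels, rows, cols) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 1 || cols < 1) {
    mrs_parameter_error("'rows' and 'cols' must be >= 1")
  }
  if (length(voxels) != rows * cols ||
      !all(vapply(voxels, inherits, logical(1), "mrs_voxel"))) {
    mrs_parameter_error("'voxels' must be a list of rows*cols mrs_voxel objects")
  }
  n0 <- length(voxels[[1]]$spectrum$intensities)
  ax0 <- voxels[[1]]$spectrum$axis
  for (i in seq_along(voxels)) {
    sp <- voxels[[i]]$spectrum
    if (length(sp$intensities) != n0 || !isTRUE(all.equal(sp$axis, ax0))) {
      mrs_validation_error("all grid voxels must share the same ppm axis")
    }
    r <- (i - 1L) %/% cols + 1L
    c <- (i - 1L) %% cols + 1L
    voxels[[i]]$position <- c(c, r, 1L)  # (Xaxis=col, Yaxis=row, Zaxis=1)
  }
  structure(list(voxels = voxels, rows = rows, cols = cols),
            class = "mrs_grid")
}

#' Extract one voxel from a grid by matrix position
#'
#' @param grid An [grid_record()] object.
#' @param row,col 1-based matrix indices (top-left is `[1, 1]`).
#' @return The [voxel_record()] at that position.
#' @export
grid_voxel <- function(grid, row, col) {
  stopifnot(inherits(grid, "mrs_grid"))
  if (row < 1 || row > grid$rows || col < 1 || col > grid$cols) {
    mrs_parameter_error(sprintf(
      "position [%s, %s] outside the %d x %d grid", row, col,
      grid$rows, grid$cols
    ))
  }
  grid$voxels[[(as.integer(row) - 1L) * grid$cols + as.integer(col)]]
}

#' Root dataset: provenance plus exactly one payload
#'
#' A dataset pairs one preprocessing record with exactly one payload:
#' either a single voxel or a grid, never both.
#'
#' @param preprocessing An [preprocessing_record()] object.
#' @param payload An [voxel_record()] (single voxel) or [grid_record()]
#'   (multi-voxel) object.
#' @return An object of class `mrs_dataset`.
#' @export
mrs_dataset <- function(preprocessing, payload) {
  if (!inherits(preprocessing, "mrs_preprocessing")) {
    mrs_validation_error("'preprocessing' must be an mrs_preprocessing object")
  }
  is_sv <- inherits(payload, "mrs_voxel")
  is_mv <- inherits(payload, "mrs_grid")
  if (!xor(is_sv, is_mv)) {
    mrs_validation_error(
      "a dataset holds exactly one payload: a voxel (SV) or a grid (MV)"
    )
  }
  structure(
    list(preprocessing = preprocessing, payload = payload,
         kind = if (is_sv) "SV" else "MV"),
    class = "mrs_dataset"
  )
}

#' @export
print.mrs_dataset <- function(x, ...) {
  if (x$kind == "SV") {
    cat(sprintf("MRS dataset (SV): %d points, %d preprocessing step(s)\n",
                length(x$payload$spectrum$intensities),
                length(x$preprocessing$steps)))
  } else {
    cat(sprintf("MRS dataset (MV): %d x %d grid, %d preprocessing step(s)\n",
                x$payload$rows, x$payload$cols, length(x$preprocessing$steps)))
  }
  invisible(x)
}
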