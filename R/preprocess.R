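# The eight preprocessing operators plus SNR computation and the
# output-range crop.  Steps are always executed in the fixed pipeline
# order (lower numbers first); each operator appends one provenance
# record holding exactly its inputs, so a recorded pipeline can be
# replayed bit-for-bit on the same raw input.

# Tolerance used when resolving closed ppm intervals against an axis:
# absorbs floating-point error in axis construction (axis spacings are
# ~1e-2 ppm, ten orders of magnitude larger).
PPM_EPS <- 1e-9

range_mask <- function(axis, range) {
  axis >= range$lower - PPM_EPS & axis <= range$upper + PPM_EPS
}

check_regions <- function(regions, max_n, what) {
  if (is_ppm_range(regions)) regions <- list(regions)
  if (length(regions) < 1 || length(regions) > max_n ||
      !all(vapply(regions, is_ppm_range, logical(1)))) {
    mrs_parameter_error(sprintf(
      "%s takes between 1 and %d ppm ranges", what, max_n
    ))
  }
  regions
}

## ---- Step I: Set Reference ------------------------------------------

#' Step I: assign a new ppm reference to the carrier
#'
#' Re-labels the ppm axis so that the carrier (centre bin) carries
#' `new_reference`; for example 4.75 ppm for unsuppressed water in
#' proton spectra.  Intensities are unchanged: this step only moves the
#' axis, it does not shift the data.
#'
#' @param spec An [spectrum()] object.
#' @param new_reference New carrier reference in ppm.
#' @return The re-referenced spectrum with one provenance record
#'   appended.
#' @export
set_reference <- function(spec, new_reference) {
  stopifnot(inherits(spec, "mrs_spectrum"))
  if (!is.numeric(new_reference) || length(new_reference) != 1 ||
      !is.finite(new_reference)) {
    mrs_parameter_error("'new_reference' must be a single finite ppm value")
  }
  p <- spec$params
  p$reference_ppm <- as.numeric(new_reference)
  out <- carry_steps(spectrum(spec$intensities, p), spec)
  append_step(out, "SetReference", list(reference = as.numeric(new_reference)))
}

## ---- Step II: Apodize -----------------------------------------------

#' Step II: apodization (line broadening) in the time domain
#'
#' Multiplies the FID by a decaying window.  The Lorentzian window
#' `exp(-pi * lw * t)` adds `lw` Hz to the full width at half maximum
#' of a Lorentzian line; the Gaussian window
#' `exp(-(pi * lw * t)^2 / (4 log 2))` produces a Gaussian contribution
#' of FWHM `lw` Hz.  The first sample (`t = 0`) is always unchanged.
#'
#' @param sig An [time_signal()] object.
#' @param shape `"Lorentzian"` or `"Gaussian"`.
#' @param linewidth Line broadening in Hz; must be >= 0.
#' @return The apodized FID with one provenance record appended.
#' @export
apodize <- function(sig, shape = c("Lorentzian", "Gaussian"), linewidth) {
  stopifnot(inherits(sig, "mrs_fid"))
  shape <- match.arg(shape)
  if (!is.numeric(linewidth) || length(linewidth) != 1 ||
      !is.finite(linewidth) || linewidth < 0) {
    mrs_parameter_error("'linewidth' must be a single non-negative number (Hz)")
  }
  t <- seq.int(0L, length(sig$samples) - 1L) * dwell_time(sig$params)
  w <- if (shape == "Lorentzian") {
    exp(-pi * linewidth * t)
  } else {
    exp(-(pi * linewidth * t)^2 / (4 * log(2)))
  }
  out <- carry_steps(time_signal(sig$samples * w, sig$params), sig)
  append_step(out, "Apodize",
              list(shape = shape, linewidth = as.numeric(linewidth)))
}

## ---- Step III: Water Filtering (HLSVD) ------------------------------

#' Step III: HLSVD filtering of selected spectral regions
#'
#' Fits `n_lorentzians` damped complex sinusoids to the FID (see
#' [fit_components()]) and subtracts those whose frequencies fall inside
#' any of up to three ppm regions.  Most commonly used to remove the
#' residual water signal in proton spectra, but any signal can be
#' filtered by choosing the regions.
#'
#' @param sig An [time_signal()] object.
#' @param n_lorentzians Number of Lorentzian components to fit.
#' @param regions One [ppm_range()] or a list of up to three.
#' @return The filtered FID with one provenance record appended.
#' @export
hlsvd_filter <- function(sig, n_lorentzians, regions) {
  stopifnot(inherits(sig, "mrs_fid"))
  regions <- check_regions(regions, 3L, "water filtering")
  comps <- fit_components(sig, n_lorentzians)
  sel <- select_in_regions(comps, regions, sig$params)
  resid <- sig$samples - reconstruct_fid(sel, sig$params)$samples
  out <- carry_steps(time_signal(resid, sig$params), sig)
  append_step(out, "WaterFiltering",
              list(n_lorentzians = as.integer(n_lorentzians), regions = regions))
}

## ---- Step IV: Baseline Correction -----------------------------------

#' Step IV: constant baseline correction from reference regions
#'
#' Takes the mean intensity within each of up to three ppm regions, then
#' the mean of those per-region means, and subtracts that single value
#' from every spectral point.  Appropriate only for baselines that are
#' not sloped.
#'
#' @param spec An [spectrum()] object.
#' @param regions One [ppm_range()] or a list of up to three; each must
#'   contain at least one spectral point.
#' @return The corrected spectrum with one provenance record appended.
#' @export
baseline_correct <- function(spec, regions) {
  stopifnot(inherits(spec, "mrs_spectrum"))
  regions <- check_regions(regions, 3L, "baseline correction")
  region_means <- vapply(regions, function(r) {
    m <- range_mask(spec$axis, r)
    if (!any(m)) {
      mrs_parameter_error(sprintf(
        "baseline region [%g, %g] ppm contains no spectral points",
        r$lower, r$upper
      ))
    }
    mean(spec$intensities[m])
  }, complex(1))
  corr <- mean(region_means)
  out <- carry_steps(spectrum(spec$intensities - corr, spec$params), spec)
  append_step(out, "BaselineCorrection", list(regions = regions))
}

## ---- Step V: Change number of points in range -----------------------

# Zero fill the FID to double length; same sweep width, so the ppm grid
# halves its spacing while keeping the same span and carrier value.
zero_fill_double <- function(spec) {
  fid <- to_time_domain(spec)
  p <- fid$params
  p$num_points <- 2L * p$num_points
  padded <- carry_steps(
    time_signal(c(fid$samples, complex(length(fid$samples))), p), fid
  )
  to_frequency_domain(padded)
}

#' Step V: enforce a point count within a ppm range
#'
#' Guarantees that exactly `target_points` spectral points lie inside
#' the closed interval `range`, homogenizing resolution across scanners.
#' If the range currently holds more points, the frequency vector is
#' undersampled by skipping values (each point of a uniform target grid
#' takes the nearest original point -- raw values, no interpolation);
#' if fewer, the FID is zero filled in the time domain (doubling the
#' length as often as needed) before decimation.  The full original ppm
#' span is retained, resampled on the same uniform grid; use
#' [output_range()] (Step IX) to crop.
#'
#' @param spec An [spectrum()] object.
#' @param target_points Desired number of points in `range` (>= 2).
#' @param range An [ppm_range()] lying within the spectral axis span.
#' @return The resampled spectrum with one provenance record appended.
#' @export
change_points_in_range <- function(spec, target_points, range) {
  stopifnot(inherits(spec, "mrs_spectrum"))
  if (!is_ppm_range(range)) {
    mrs_parameter_error("'range' must be a ppm_range object")
  }
  if (!is.numeric(target_points) || length(target_points) != 1 ||
      target_points != round(target_points) || target_points < 2) {
    mrs_parameter_error("'target_points' must be an integer >= 2")
  }
  target_points <- as.integer(target_points)
  ax <- spec$axis
  if (range$upper > ax[1] + PPM_EPS || range$lower < ax[length(ax)] - PPM_EPS) {
    mrs_parameter_error(sprintf(
      "range [%g, %g] ppm extends outside the spectral axis [%g, %g]",
      range$lower, range$upper, ax[length(ax)], ax[1]
    ))
  }
  rec <- list(target_points = target_points, range = range)
  cur <- spec
  count <- sum(range_mask(cur$axis, range))
  if (count == target_points) {
    return(append_step(cur, "ChangePoints", rec))
  }
  while (count < target_points) {
    cur <- zero_fill_double(cur)
    count <- sum(range_mask(cur$axis, range))
  }
  if (count == target_points) {
    return(append_step(cur, "ChangePoints", rec))
  }
  # Uniform target grid: target_points across the range, extended at the
  # same spacing to cover the full original span.
  step <- (range$upper - range$lower) / (target_points - 1L)
  ax <- cur$axis
  n_up <- floor((ax[1] - range$upper) / step + PPM_EPS)
  n_dn <- floor((range$lower - ax[length(ax)]) / step + PPM_EPS)
  coords <- c(
    range$upper + step * seq.int(n_up, 1L, length.out = max(n_up, 0L)),
    range$upper - step * seq.int(0L, target_points - 1L),
    range$lower - step * seq_len(max(n_dn, 0L))
  )
  # Nearest original point for each target coordinate (ties take the
  # lower index, i.e. the higher-ppm neighbour).
  orig_step <- ax[1] - ax[2]
  pos <- (ax[1] - coords) / orig_step + 1
  idx <- pmin(pmax(ceiling(pos - 0.5), 1L), length(ax))
  n_new <- length(coords)
  p <- cur$params
  p$num_points <- n_new
  p$sweep_width <- step * p$transmitter_frequency * n_new
  p$reference_ppm <- coords[carrier_index0(n_new) + 1L]
  out <- carry_steps(spectrum(cur$intensities[idx], p), cur)
  append_step(out, "ChangePoints", rec)
}

## ---- Step VI: Set to zero -------------------------------------------

#' Step VI: zero the spectrum inside ppm intervals
#'
#' Sets the spectral points lying in up to two closed ppm intervals to
#' complex zero, e.g. to make a poorly suppressed residual water
#' contribution negligible before unit-length normalization.
#'
#' @param spec An [spectrum()] object.
#' @param intervals One [ppm_range()] or a list of up to two.
#' @return The modified spectrum with one provenance record appended.
#' @export
set_to_zero <- function(spec, intervals) {
  stopifnot(inherits(spec, "mrs_spectrum"))
  intervals <- check_regions(intervals, 2L, "set to zero")
  x <- spec$intensities
  for (r in intervals) x[range_mask(spec$axis, r)] <- 0 + 0i
  out <- carry_steps(spectrum(x, spec$params), spec)
  append_step(out, "SetToZero", list(intervals = intervals))
}

## ---- Step VII: l2 (unit-length) normalization -----------------------

#' Step VII: l2 (unit-length) normalization
#'
#' Divides every spectral value by the l2 norm
#' `|x| = sqrt(sum_k |x_k|^2)`, bringing spectra from scanners with
#' arbitrary intensity units onto the same relative scale.  The
#' resulting vector has unit norm; the operation is idempotent.
#'
#' @param spec An [spectrum()] object; must not be all-zero.
#' @return The normalized spectrum with one provenance record appended.
#' @export
l2_normalize <- function(spec) {
  stopifnot(inherits(spec, "mrs_spectrum"))
  nrm <- sqrt(sum(Mod(spec$intensities)^2))
  if (nrm == 0) {
    mrs_numerics_error("cannot l2-normalize an all-zero spectrum")
  }
  out <- carry_steps(spectrum(spec$intensities / nrm, spec$params), spec)
  append_step(out, "Normalization", list(type = "l2"))
}

## ---- SNR -------------------------------------------------------------

#' Signal-to-noise ratio of a spectrum
#'
#' `SNR = Max Peak / (2 * STD(noise))`, where Max Peak is the highest
#' amplitude (complex magnitude) over the chosen scope and STD(noise)
#' the standard deviation over a user-designated noise region (computed
#' on the real part, matching the display amplitude convention).
#'
#' @param spec An [spectrum()] object.
#' @param noise An [noise_region()] resolving to at least two spectral
#'   points.
#' @param peak_scope `NULL` for the whole spectrum (the default, used
#'   for per-voxel SNR reporting), or an integer vector of spectral
#'   indices restricting the Max Peak search (used by the alignment
#'   step's per-peak windows).
#' @return An object of class `mrs_snr` with fields `snr`, `max_peak`
#'   and `noise_std`.
#' @export
compute_snr <- function(spec, noise, peak_scope = NULL) {
  stopifnot(inherits(spec, "mrs_spectrum"))
  if (is_ppm_range(noise)) noise <- noise_region(noise)
  if (!is_noise_region(noise)) {
    mrs_parameter_error("'noise' must be a noise_region (or ppm_range) object")
  }
  m <- range_mask(spec$axis, noise$range)
  if (sum(m) < 2) {
    mrs_parameter_error("noise region must contain at least 2 spectral points")
  }
  noise_std <- stats::sd(Re(spec$intensities[m]))
  if (noise_std == 0) {
    mrs_numerics_error("degenerate noise region: zero standard deviation")
  }
  scope <- if (is.null(peak_scope)) seq_along(spec$intensities) else peak_scope
  max_peak <- max(Mod(spec$intensities[scope]))
  structure(
    list(snr = max_peak / (2 * noise_std), max_peak = max_peak,
         noise_std = noise_std),
    class = "mrs_snr"
  )
}

## ---- Step VIII: Alignment Correction --------------------------------

# The alignment search radius is fixed: at most 10 points either way in
# the frequency vector (a smaller ppm window for higher resolutions).
ALIGN_MAX_SHIFT <- 10L

#' Alignment specification for Step VIII
#'
#' @param peaks Numeric vector of theoretical peak positions in ppm;
#'   must be non-empty.  With `brain_1p5T_preset`, supply the positions
#'   from a site-maintained preset file (see [load_peak_list()]); the
#'   package ships no hard-coded preset.
#' @param noise An [noise_region()] (or bare [ppm_range()]) used for the
#'   SNR that selects among candidate peaks.
#' @param brain_1p5T_preset Logical flag recording that the peak list
#'   came from the 1.5 T brain proton preset.
#' @return An object of class `mrs_alignment`.
#' @export
alignment_spec <- function(peaks, noise, brain_1p5T_preset = FALSE) {
  if (!is.numeric(peaks) || length(peaks) < 1 || any(!is.finite(peaks))) {
    mrs_parameter_error("'peaks' must be a non-empty numeric vector of ppm values")
  }
  if (is_ppm_range(noise)) noise <- noise_region(noise)
  if (!is_noise_region(noise)) {
    mrs_parameter_error("'noise' must be a noise_region (or ppm_range) object")
  }
  structure(
    list(peaks = as.numeric(peaks), noise = noise,
         max_shift = ALIGN_MAX_SHIFT,
         brain_1p5T_preset = isTRUE(brain_1p5T_preset)),
    class = "mrs_alignment"
  )
}

#' Load a theoretical peak list from a text file
#'
#' One ppm value per line; blank lines and `#` comments are ignored.
#' Used to supply the brain-proton preset peak positions, which are a
#' site configuration rather than a package constant.
#'
#' @param path Path to the peak-list file.
#' @return Numeric vector of ppm values.
#' @export
load_peak_list <- function(path) {
  if (!file.exists(path)) {
    mrs_io_error(sprintf("peak list file not found: %s", path))
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  peaks <- suppressWarnings(as.numeric(lines))
  if (length(peaks) == 0 || any(is.na(peaks))) {
    mrs_validation_error(sprintf("invalid peak list file: %s", path))
  }
  peaks
}

#' Step VIII: alignment correction against theoretical peak positions
#'
#' For each theoretical peak the SNR is evaluated with Max Peak
#' restricted to a window of +/-10 points around the peak's theoretical
#' axis index; the peak with the highest SNR is selected and the
#' spectrum is shifted by the integer number of points (at most 10)
#' that places that peak's local maximum on its theoretical index.  The
#' shift is circular with the wrapped edge points set to zero, so no
#' data is invented at the boundary.
#'
#' @param spec An [spectrum()] object.
#' @param alignment An [alignment_spec()] object.
#' @return The aligned spectrum, with the applied shift (in points,
#'   positive towards higher index / lower ppm) available as
#'   `attr(x, "applied_shift")`, and one provenance record appended.
#' @export
align <- function(spec, alignment) {
  stopifnot(inherits(spec, "mrs_spectrum"))
  if (!inherits(alignment, "mrs_alignment")) {
    mrs_parameter_error("'alignment' must be an alignment_spec object")
  }
  n <- length(spec$intensities)
  mags <- Mod(spec$intensities)
  best <- NULL
  for (p in alignment$peaks) {
    t_idx <- which.min(abs(spec$axis - p))
    win <- max(1L, t_idx - ALIGN_MAX_SHIFT):min(n, t_idx + ALIGN_MAX_SHIFT)
    snr_p <- compute_snr(spec, alignment$noise, peak_scope = win)
    if (is.null(best) || snr_p$snr > best$snr) {
      best <- list(snr = snr_p$snr, t_idx = t_idx, win = win)
    }
  }
  m_idx <- best$win[which.max(mags[best$win])]
  shift <- best$t_idx - m_idx
  x <- spec$intensities
  if (shift != 0) {
    x <- x[((seq_len(n) - 1L - shift) %% n) + 1L]
    if (shift > 0) x[seq_len(shift)] <- 0 + 0i
    else x[seq.int(n + shift + 1L, n)] <- 0 + 0i
  }
  out <- carry_steps(spectrum(x, spec$params), spec)
  out <- append_step(out, "AlignmentCorrection", list(
    peaks = alignment$peaks,
    noise = alignment$noise$range,
    brain_1p5T_preset = alignment$brain_1p5T_preset
  ))
  attr(out, "applied_shift") <- as.integer(shift)
  out
}

## ---- Step IX: Output range ------------------------------------------

#' Step IX: crop the output to a ppm range
#'
#' Truncates the spectrum to the points inside the closed interval
#' `range`.  Needed when harmonizing data from machines with different
#' ppm spans: without it, spectra with equal point counts but slightly
#' different spans produce output vectors of different lengths.
#'
#' @param spec An [spectrum()] object.
#' @param range An [ppm_range()] overlapping the axis.
#' @return The cropped spectrum with one provenance record appended.
#' @export
output_range <- function(spec, range) {
  stopifnot(inherits(spec, "mrs_spectrum"))
  if (!is_ppm_range(range)) {
    mrs_parameter_error("'range' must be a ppm_range object")
  }
  keep <- which(range_mask(spec$axis, range))
  if (length(keep) == 0) {
    mrs_parameter_error(sprintf(
      "no spectral points inside the output range [%g, %g] ppm",
      range$lower, range$upper
    ))
  }
  ax_new <- spec$axis[keep]
  n_new <- length(keep)
  p <- spec$params
  p$num_points <- n_new
  if (n_new >= 2) {
    step <- ax_new[1] - ax_new[2]
    p$sweep_width <- step * p$transmitter_frequency * n_new
  }
  p$reference_ppm <- ax_new[carrier_index0(n_new) + 1L]
  out <- carry_steps(spectrum(spec$intensities[keep], p), spec)
  append_step(out, "OutputRange", list(range = range))
}
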