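# Synthetic proton-like FID generator with known ground truth, so every
# operator and the full pipeline can be tested without acquired data.
# FIDs are sums of exponentially damped complex sinusoids (one per
# peak) plus i.i.d. circular complex Gaussian noise -- the standard MRS
# noise assumption, which keeps frequency-domain noise Gaussian too.

# Evaluate and restore the RNG state around a seeded draw so generators
# are pure functions of (parameters, seed).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Build a peak table for the synthetic generator
#'
#' @param ppm,amplitude,damping,phase Equal-length numeric vectors: peak
#'   position (ppm), non-negative amplitude (arbitrary units),
#'   Lorentzian damping rate (1/s; FWHM is `damping / pi` Hz) and phase
#'   (radians).
#' @return A data frame with one row per peak.
#' @export
peak_model <- function(ppm, amplitude, damping, phase = 0) {
  if (any(amplitude < 0)) {
    mrs_parameter_error("peak amplitudes must be non-negative")
  }
  data.frame(ppm = ppm, amplitude = amplitude, damping = damping,
             phase = rep_len(phase, length(ppm)))
}

#' Generate a synthetic FID from a peak table
#'
#' Each peak contributes an exponentially damped complex sinusoid at
#' the baseband frequency implied by its ppm position and the carrier
#' reference; i.i.d. circular complex Gaussian noise of standard
#' deviation `noise_sd` per quadrature channel is added on top.
#' Deterministic for a fixed seed.
#'
#' @param peaks Data frame as returned by [peak_model()] (columns
#'   `ppm`, `amplitude`, `damping`, `phase`); may have zero rows.
#' @param params An [acquisition_params()] object.
#' @param noise_sd Noise standard deviation per quadrature channel;
#'   0 for a noiseless FID.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return An [time_signal()] object with the ground-truth peak table
#'   attached as `attr(x, "peaks")`.
#' @export
gen_fid <- function(peaks, params, noise_sd = 0, seed = NULL) {
  if (!is_params(params)) {
    mrs_parameter_error("'params' must be an acquisition_params object")
  }
  comps <- data.frame(
    amplitude = peaks$amplitude,
    phase = if ("phase" %in% names(peaks)) peaks$phase else rep(0, NROW(peaks)),
    frequency = ppm_to_hz(peaks$ppm, params),
    damping = peaks$damping
  )
  s <- reconstruct_fid(comps, params)$samples
  if (noise_sd > 0) {
    noise <- with_seed(seed, complex(
      real = stats::rnorm(params$num_points, sd = noise_sd),
      imaginary = stats::rnorm(params$num_points, sd = noise_sd)
    ))
    s <- s + noise
  }
  out <- time_signal(s, params)
  attr(out, "peaks") <- peaks
  out
}

# Peak positions loosely emulating a short-TE proton brain spectrum:
# residual water dominating at 4.7 ppm plus a few metabolite singlets.
# These are fixture choices for exercising water filtering and
# alignment, not a quantitative metabolite basis set.
brain_like_peaks <- function() {
  peak_model(
    ppm = c(4.70, 3.21, 3.03, 2.01, 1.33),
    amplitude = c(50, 6, 5, 8, 4),
    damping = c(12, 10, 10, 10, 14),
    phase = 0
  )
}

#' Generate a brain-like single-voxel FID
#'
#' A dominant residual-water peak near 4.7 ppm plus several smaller
#' metabolite-like peaks (choline, creatine, N-acetylaspartate,
#' lactate positions) and complex Gaussian noise.  The ground-truth
#' peak table is attached as `attr(x, "peaks")` so tests never have to
#' re-derive it.
#'
#' @param params An [acquisition_params()] object.
#' @param seed Integer seed for the noise draw.
#' @param noise_sd Noise standard deviation per quadrature channel.
#' @param amplitude_scale Multiplier applied to all peak amplitudes
#'   (used by [gen_mv_grid()] to alter voxels under a lesion mask).
#' @return An [time_signal()] object with ground truth attached.
#' @export
gen_brain_like_sv <- function(params, seed = NULL, noise_sd = 0.05,
                              amplitude_scale = 1) {
  peaks <- brain_like_peaks()
  peaks$amplitude <- peaks$amplitude * amplitude_scale
  gen_fid(peaks, params, noise_sd = noise_sd, seed = seed)
}

#' Generate a synthetic multi-voxel grid
#'
#' A `rows` x `cols` grid of brain-like voxels (see
#' [gen_brain_like_sv()]).  Voxels flagged in `lesion_mask` get altered
#' peak amplitudes (reduced N-acetylaspartate, raised choline --
#' a crude tumour-like contrast).  All labels start as `"***"`; use
#' [set_voxel_label()] to label voxels.  Deterministic for a fixed
#' seed.
#'
#' @param rows,cols Grid dimensions (>= 1).
#' @param params An [acquisition_params()] object shared by all voxels.
#' @param lesion_mask Optional logical matrix of dimension
#'   `rows x cols`; `TRUE` marks lesion-like voxels.
#' @param seed Integer seed.
#' @param noise_sd Noise standard deviation per quadrature channel.
#' @return An [grid_record()] whose voxel spectra are the plain Fourier
#'   transforms of the generated FIDs (zero preprocessing steps), with
#'   the per-voxel ground-truth peak tables attached as
#'   `attr(x, "ground_truth")` (row-major list).
#' @export
gen_mv_grid <- function(rows, cols, params, lesion_mask = NULL, seed = NULL,
                        noise_sd = 0.05) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 1 || cols < 1) {
    mrs_parameter_error("'rows' and 'cols' must be >= 1")
  }
  if (!is.null(lesion_mask) &&
      (!is.logical(lesion_mask) || !all(dim(lesion_mask) == c(rows, cols)))) {
    mrs_parameter_error("'lesion_mask' must be a rows x cols logical matrix")
  }
  with_seed(seed, {
    voxels <- vector("list", rows * cols)
    truth <- vector("list", rows * cols)
    for (r in seq_len(rows)) {
      for (cc in seq_len(cols)) {
        i <- (r - 1L) * cols + cc
        peaks <- brain_like_peaks()
        if (!is.null(lesion_mask) && lesion_mask[r, cc]) {
          peaks$amplitude[peaks$ppm == 2.01] <-
            peaks$amplitude[peaks$ppm == 2.01] * 0.3
          peaks$amplitude[peaks$ppm == 3.21] <-
            peaks$amplitude[peaks$ppm == 3.21] * 2.5
        }
        fid <- gen_fid(peaks, params, noise_sd = noise_sd, seed = NULL)
        voxels[[i]] <- voxel_record(to_frequency_domain(fid))
        truth[[i]] <- peaks
      }
    }
    out <- grid_record(voxels, rows, cols)
    attr(out, "ground_truth") <- truth
    out
  })
}
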