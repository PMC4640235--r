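# Domain conversion.  The forward DFT is unscaled and the inverse
# carries the 1/n factor; under this convention
# sum(|FID|^2) == sum(|spectrum|^2) / n (Parseval).
#
# After the transform the spectrum is rotated so that index 1 holds the
# highest ppm (most positive baseband frequency): spectral index k
# (0-based) takes FFT bin (floor(n/2) - k) mod n, matching the axis
# convention of build_ppm_axis().

spectral_bin_map <- function(n) {
  ((carrier_index0(n) - seq.int(0L, n - 1L)) %% n) + 1L
}

#' Transform a time-domain FID to a frequency-domain spectrum
#'
#' Computes the discrete Fourier transform of the FID and rotates the
#' half-spectra so that index 1 corresponds to the highest ppm value
#' (left edge of the conventional MRS display).  [to_time_domain()] is
#' its exact inverse.  Provenance recorded on the input is carried over.
#'
#' @param sig An [time_signal()] object.
#' @return An [spectrum()] object on the ppm axis implied by
#'   `sig$params`.
#' @export
to_frequency_domain <- function(sig) {
  if (!inherits(sig, "mrs_fid")) {
    mrs_parameter_error("'sig' must be an mrs_fid object")
  }
  X <- stats::fft(sig$samples)
  sp <- spectrum(X[spectral_bin_map(length(X))], sig$params)
  carry_steps(sp, sig)
}

#' Transform a spectrum back to the time domain
#'
#' Exact inverse of [to_frequency_domain()] (the inverse DFT carries the
#' `1/n` scaling).  Provenance recorded on the input is carried over.
#'
#' @param spec An [spectrum()] object.
#' @return An [time_signal()] object.
#' @export
to_time_domain <- function(spec) {
  if (!inherits(spec, "mrs_spectrum")) {
    mrs_parameter_error("'spec' must be an mrs_spectrum object")
  }
  n <- length(spec$intensities)
  X <- complex(n)
  X[spectral_bin_map(n)] <- spec$intensities
  sig <- time_signal(stats::fft(X, inverse = TRUE) / n, spec$params)
  carry_steps(sig, spec)
}
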