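# HSVD/HLSVD subspace modelling of an FID as a sum of exponentially
# damped complex sinusoids, used by the water-filtering step to remove
# selected components (typically residual water) from the time-domain
# signal.

#' Fit damped complex sinusoids to an FID (HLSVD / HSVD)
#'
#' Models the FID as
#' \deqn{s_t = \sum_j a_j e^{i\phi_j} e^{(i 2\pi f_j - d_j) t},}
#' one term per "Lorentzian".  A Hankel matrix of the signal
#' (`floor(n/2)` rows) is decomposed by SVD truncated at
#' `model_order`; the signal poles follow from the shift invariance of
#' the dominant left-singular subspace (solved by least squares), the
#' frequencies and dampings from the pole angles and magnitudes, and
#' the amplitudes and phases from a final linear least-squares fit
#' against the FID.
#'
#' @param sig An [time_signal()] object.
#' @param model_order Number of Lorentzian components (SVD truncation
#'   rank); must satisfy `1 <= model_order < n/2`.
#' @return A data frame with one row per component and columns
#'   `amplitude`, `phase` (radians), `frequency` (Hz, signed baseband
#'   offset), `damping` (1/s), `ppm` (frequency converted to ppm via
#'   the carrier reference) and `physical` (`FALSE` flags growing,
#'   negative-damping components: legal fit output, not physically
#'   meaningful).
#' @export
#' @examples
#' p <- acquisition_params(1, 1000, 256, reference_ppm = 0)
#' fid <- gen_fid(data.frame(ppm = 0.1, amplitude = 1, damping = 20, phase = 0),
#'                p, noise_sd = 0)
#' fit_components(fid, 1)
fit_components <- function(sig, model_order) {
  if (!inherits(sig, "mrs_fid")) {
    mrs_parameter_error("'sig' must be an mrs_fid object")
  }
  s <- sig$samples
  n <- length(s)
  if (!is.numeric(model_order) || length(model_order) != 1 ||
      model_order != round(model_order) || model_order < 1) {
    mrs_parameter_error("'model_order' must be a positive integer")
  }
  if (model_order >= n / 2) {
    mrs_parameter_error(sprintf(
      "model_order (%d) must be below n/2 = %g", model_order, n / 2
    ))
  }
  if (sum(Mod(s)) == 0) {
    mrs_numerics_error("all-zero FID: no signal subspace to decompose")
  }
  K <- as.integer(model_order)
  L <- n %/% 2L              # Hankel rows; near-square maximizes rank
  M <- n - L + 1L
  H <- matrix(s[outer(seq_len(L), seq_len(M), function(i, j) i + j - 1L)],
              nrow = L, ncol = M)
  dec <- svd(H, nu = K, nv = 0)
  if (sum(dec$d > max(dec$d) * 1e-12) < K) {
    mrs_numerics_error(sprintf(
      "signal subspace is rank deficient: fewer than %d significant singular values",
      K
    ))
  }
  U <- dec$u
  Ut <- U[-L, , drop = FALSE]   # rows 1..L-1
  Ub <- U[-1L, , drop = FALSE]  # rows 2..L
  # Shift-invariance: Ub ~= Ut %*% Z; poles are the eigenvalues of Z.
  Z <- qr.solve(Ut, Ub)
  z <- eigen(Z, only.values = TRUE)$values
  dt <- dwell_time(sig$params)
  freq <- Arg(z) / (2 * pi * dt)
  damp <- -log(Mod(z)) / dt
  # Amplitudes/phases: linear LS of the FID on the pole basis.
  V <- exp(outer(seq.int(0L, n - 1L) * dt, complex(imaginary = 2 * pi * freq) - damp))
  cvec <- qr.solve(V, s)
  out <- data.frame(
    amplitude = Mod(cvec),
    phase = Arg(cvec),
    frequency = freq,
    damping = damp
  )
  out$ppm <- hz_to_ppm(out$frequency, sig$params)
  # growing (negative-damping) components are legal fit output but are
  # not physically meaningful; flag them for the caller
  out$physical <- out$damping >= 0
  out[order(-out$amplitude), , drop = FALSE]
}

#' Reconstruct an FID from fitted damped sinusoids
#'
#' @param components Data frame as returned by [fit_components()]
#'   (columns `amplitude`, `phase`, `frequency`, `damping`).
#' @param params An [acquisition_params()] object defining the sampling
#'   grid.
#' @return An [time_signal()] object,
#'   \eqn{s_t = \sum_j a_j e^{i\phi_j} e^{(i 2\pi f_j - d_j) t}};
#'   the all-zero FID for an empty component list.
#' @export
reconstruct_fid <- function(components, params) {
  if (!is_params(params)) {
    mrs_parameter_error("'params' must be an acquisition_params object")
  }
  t <- seq.int(0L, params$num_points - 1L) * dwell_time(params)
  s <- complex(params$num_points)
  for (j in seq_len(NROW(components))) {
    s <- s + components$amplitude[j] *
      exp(complex(imaginary = components$phase[j])) *
      exp((complex(imaginary = 2 * pi * components$frequency[j]) -
             components$damping[j]) * t)
  }
  time_signal(s, params)
}

#' Select fitted components lying inside ppm regions
#'
#' Component frequencies are converted to ppm via the carrier reference
#' (`ppm = reference_ppm + f / transmitter_frequency`, the sign fixed by
#' the package's axis orientation) and kept when they fall inside any of
#' the closed regions.
#'
#' @param components Data frame as returned by [fit_components()].
#' @param regions List of [ppm_range()] objects.
#' @param params An [acquisition_params()] object.
#' @return The subset of `components` whose ppm position lies in at
#'   least one region.
#' @export
select_in_regions <- function(components, regions, params) {
  if (!is_params(params)) {
    mrs_parameter_error("'params' must be an acquisition_params object")
  }
  if (!all(vapply(regions, is_ppm_range, logical(1)))) {
    mrs_parameter_error("'regions' must be a list of ppm_range objects")
  }
  ppm <- hz_to_ppm(components$frequency, params)
  keep <- rep(FALSE, NROW(components))
  for (r in regions) keep <- keep | (ppm >= r$lower & ppm <= r$upper)
  components[keep, , drop = FALSE]
}
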