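test_that("set reference relabels the axis so water sits at 4.75 ppm", {
  p <- proton_params(512)
  sp <- to_frequency_domain(water_on_carrier(p))
  out <- set_reference(sp, 4.75)
  expect_equal(out$axis[which.max(Mod(out$intensities))], 4.75)
  expect_identical(out$intensities, sp$intensities)
  # axis maximum = new reference + half span (centre-to-left arithmetic)
  step <- p$sweep_width / (p$transmitter_frequency * p$num_points)
  expect_equal(max(out$axis), 4.75 + (512 %/% 2) * step, tolerance = 1e-12)
  # identity when the reference does not change
  same <- set_reference(sp, p$reference_ppm)
  expect_equal(same$axis, sp$axis)
  expect_identical(step_ids(out), "SetReference")
})

test_that("apodization windows behave as documented", {
  p <- proton_params(1024)
  fid <- gen_fid(peak_model(ppm = 4.7, amplitude = 1, damping = 10), p)
  # zero linewidth is the identity
  expect_equal(apodize(fid, "Lorentzian", 0)$samples, fid$samples)
  expect_equal(apodize(fid, "Gaussian", 0)$samples, fid$samples)
  # the first sample (t = 0) is never attenuated
  for (lw in c(1, 5, 20)) {
    expect_equal(apodize(fid, "Lorentzian", lw)$samples[1], fid$samples[1])
    expect_equal(apodize(fid, "Gaussian", lw)$samples[1], fid$samples[1])
  }
  expect_error(apodize(fid, "Lorentzian", -1), class = "mrs_parameter_error")
})

test_that("Lorentzian apodization adds its linewidth to the spectral FWHM", {
  # high-resolution noiseless Lorentzian line; FWHM measured on the
  # absorption (real) part by linear interpolation at half maximum
  measure_fwhm_hz <- function(sp) {
    m <- Re(sp$intensities)
    pk <- which.max(m)
    half <- m[pk] / 2
    cross <- function(idx_seq) {
      for (i in idx_seq) {
        if (m[i] < half) {
          lo <- m[i]; hi <- m[i - sign(i - pk)]
          frac <- (half - lo) / (hi - lo)
          return(abs(i - frac * sign(i - pk) - pk))
        }
      }
      NA_real_
    }
    w <- cross(seq(pk + 1, length(m))) + cross(seq(pk - 1, 1))
    w * sp$params$sweep_width / sp$params$num_points
  }
  # fine dwell time keeps discretization broadening well below one bin
  p <- acquisition_params(63.86, 5000, 32768, reference_ppm = 4.7)
  a_hz <- 4  # damping pi*a gives a Lorentzian of FWHM a Hz
  fid <- gen_fid(peak_model(ppm = 4.7, amplitude = 1, damping = pi * a_hz), p)
  bin_hz <- p$sweep_width / p$num_points
  fwhm0 <- measure_fwhm_hz(to_frequency_domain(fid))
  expect_lt(abs(fwhm0 - a_hz), bin_hz)
  for (b_hz in c(2, 6)) {
    sp <- to_frequency_domain(apodize(fid, "Lorentzian", b_hz))
    expect_lt(abs(measure_fwhm_hz(sp) - (a_hz + b_hz)), bin_hz)
  }
})

test_that("HLSVD water filtering removes the targeted component", {
  p <- acquisition_params(63.86, 1000, 512, reference_ppm = 4.7)
  fid <- gen_fid(peak_model(ppm = 4.7, amplitude = 10, damping = 12), p)
  out <- hlsvd_filter(fid, 1, ppm_range(5.2, 4.2))
  expect_lt(sum(Mod(out$samples)^2), 1e-6 * sum(Mod(fid$samples)^2))
  expect_identical(step_ids(out), "WaterFiltering")
  # a fourth region is rejected
  four <- list(ppm_range(2, 1), ppm_range(4, 3), ppm_range(6, 5),
               ppm_range(8, 7))
  expect_error(hlsvd_filter(fid, 1, four), class = "mrs_parameter_error")
})

test_that("baseline correction subtracts the mean of per-region means", {
  p <- proton_params(100, sw = 100, f0 = 10)  # 0.1 ppm spacing
  # constant heights 2 and 4 in two disjoint regions
  ax <- build_ppm_axis(p)
  x <- complex(real = rep(0, 100))
  r1 <- ppm_range(8, 7); r2 <- ppm_range(2, 1)
  x[ax >= 7 & ax <= 8] <- 2 + 0i
  x[ax >= 1 & ax <= 2] <- 4 + 0i
  sp <- spectrum(x, p)
  out <- baseline_correct(sp, list(r1, r2))
  expect_equal(out$intensities, x - 3, tolerance = 1e-12)
  # all-zero spectrum is unchanged
  z <- spectrum(complex(100), p)
  expect_true(all(baseline_correct(z, r1)$intensities == 0))
  # random spectrum vs brute-force oracle, single region
  sp <- random_spectrum(256, seed = 4)
  r <- ppm_range(6.0, 3.0)
  out <- baseline_correct(sp, r)
  manual <- mean(sp$intensities[sp$axis >= 3.0 & sp$axis <= 6.0])
  expect_equal(out$intensities, sp$intensities - manual, tolerance = 1e-12)
  # errors: empty region, too many regions
  expect_error(baseline_correct(sp, ppm_range(40, 39)),
               class = "mrs_parameter_error")
  expect_error(
    baseline_correct(sp, list(r, r, r, r)),
    class = "mrs_parameter_error"
  )
})

test_that("change points enforces the requested count in the range", {
  p <- proton_params(2048)
  fid <- gen_brain_like_sv(p, seed = 5)
  sp <- to_frequency_domain(fid)
  w <- ppm_range(7.1, -2.7)
  out <- change_points_in_range(sp, 512, w)
  expect_equal(sum(out$axis >= -2.7 - 1e-9 & out$axis <= 7.1 + 1e-9), 512)
  # the full initial ppm span is retained (within one new-grid step)
  step_new <- out$axis[1] - out$axis[2]
  expect_lt(max(sp$axis) - max(out$axis), step_new + 1e-9)
  expect_lt(min(out$axis) - min(sp$axis), step_new + 1e-9)
  expect_identical(step_ids(out), "ChangePoints")
})

test_that("change points is the identity when the count already matches", {
  p <- proton_params(512)
  sp <- to_frequency_domain(water_on_carrier(p))
  full <- ppm_range(max(sp$axis), min(sp$axis))
  out <- change_points_in_range(sp, 512, full)
  expect_identical(out$intensities, sp$intensities)
  expect_equal(out$axis, sp$axis)
})

test_that("zero filling upsamples and preserves peak positions", {
  # 256 points in the window but 512 requested -> time-domain zero fill
  p <- proton_params(512)
  peaks <- peak_model(ppm = c(6.0, 2.0, -1.0), amplitude = c(1, 2, 1.5),
                      damping = 15)
  sp <- to_frequency_domain(gen_fid(peaks, p))
  w <- ppm_range(7.1, -2.7)
  n_before <- sum(sp$axis >= -2.7 & sp$axis <= 7.1)
  expect_lt(n_before, 512)
  out <- change_points_in_range(sp, 512, w)
  expect_equal(sum(out$axis >= -2.7 - 1e-9 & out$axis <= 7.1 + 1e-9), 512)
  # each generated line's maximum stays within one output-grid bin
  step_new <- out$axis[1] - out$axis[2]
  for (target in peaks$ppm) {
    near <- which(abs(out$axis - target) < 0.4)
    got <- out$axis[near[which.max(Mod(out$intensities[near]))]]
    expect_lt(abs(got - target), step_new + 1e-9)
  }
  # errors: range outside the axis
  expect_error(change_points_in_range(sp, 512, ppm_range(50, 40)),
               class = "mrs_parameter_error")
})

test_that("set to zero clears exactly the points inside the intervals", {
  p <- proton_params(256)
  sp <- random_spectrum(256, seed = 8)
  # whole axis -> all zero
  whole <- ppm_range(max(sp$axis) + 1, min(sp$axis) - 1)
  expect_true(all(set_to_zero(sp, whole)$intensities == 0))
  # covering no points -> unchanged
  none <- ppm_range(max(sp$axis) + 2, max(sp$axis) + 1)
  expect_identical(set_to_zero(sp, none)$intensities, sp$intensities)
  # brute-force count oracle on [4.2, 5.2]
  r <- ppm_range(5.2, 4.2)
  out <- set_to_zero(sp, r)
  idx <- which(sp$axis >= 4.2 & sp$axis <= 5.2)
  expect_gt(length(idx), 0)
  expect_true(all(out$intensities[idx] == 0))
  expect_identical(out$intensities[-idx], sp$intensities[-idx])
  # three intervals are rejected
  expect_error(set_to_zero(sp, list(r, r, r)), class = "mrs_parameter_error")
})

test_that("l2 normalization yields unit length and is idempotent", {
  p <- acquisition_params(1, 2, 2, reference_ppm = 0)
  sp <- spectrum(c(3 + 0i, 4 + 0i), p)
  out <- l2_normalize(sp)
  expect_equal(Re(out$intensities), c(0.6, 0.8), tolerance = 1e-15)
  twice <- l2_normalize(out)
  expect_equal(twice$intensities, out$intensities, tolerance = 1e-12)
  # seeded complex spectrum vs brute-force sum
  sp <- random_spectrum(512, seed = 3)
  out <- l2_normalize(sp)
  expect_equal(sum(Mod(out$intensities)^2), 1, tolerance = 1e-12)
  manual <- sp$intensities / sqrt(sum(Re(sp$intensities)^2 + Im(sp$intensities)^2))
  expect_equal(out$intensities, manual, tolerance = 1e-12)
  # all-zero spectrum cannot be normalized
  expect_error(l2_normalize(spectrum(complex(16), proton_params(16))),
               class = "mrs_numerics_error")
})

test_that("SNR equals max peak over twice the noise standard deviation", {
  p <- proton_params(100, sw = 100, f0 = 10, ref = 2)  # axis 7.0 .. -2.9
  ax <- build_ppm_axis(p)
  x <- complex(real = rep(0, 100))
  x[40] <- 10 + 0i
  noise_idx <- which(ax >= -3 & ax <= -1)
  set.seed(2)
  x[noise_idx] <- complex(real = stats::rnorm(length(noise_idx)))
  x[noise_idx] <- x[noise_idx] / stats::sd(Re(x[noise_idx]))  # sd exactly 1
  sp <- spectrum(x, p)
  res <- compute_snr(sp, noise_region(ppm_range(-1, -3)))
  expect_equal(res$noise_std, 1, tolerance = 1e-12)
  expect_equal(res$max_peak, 10)
  expect_equal(res$snr, 5, tolerance = 1e-12)
  # internal consistency of the result triple on a random spectrum
  sp <- random_spectrum(256, seed = 14)
  r <- ppm_range(-0.5, -2.5)
  res <- compute_snr(sp, r)
  idx <- which(sp$axis >= -2.5 & sp$axis <= -0.5)
  expect_equal(res$max_peak, max(Mod(sp$intensities)))
  expect_equal(res$noise_std, stats::sd(Re(sp$intensities[idx])))
  expect_equal(res$snr, res$max_peak / (2 * res$noise_std), tolerance = 1e-12)
  # degenerate noise region
  flat <- spectrum(rep(1 + 0i, 100), p)
  expect_error(compute_snr(flat, r), class = "mrs_numerics_error")
  # fewer than two points
  expect_error(compute_snr(sp, ppm_range(100, 99)),
               class = "mrs_parameter_error")
})

shifted_water <- function(shift_points, n = 512) {
  # water line displaced from its theoretical 4.7 ppm position by an
  # integer number of grid points, plus a small noise floor
  p <- proton_params(n)
  step <- p$sweep_width / (p$transmitter_frequency * n)
  gen_fid(peak_model(ppm = 4.7 + shift_points * step, amplitude = 10,
                     damping = 12),
          p, noise_sd = 0.01, seed = 99)
}

test_that("alignment moves the strongest peak onto its theoretical index", {
  noise <- ppm_range(-1, -3)
  spc <- alignment_spec(peaks = 4.7, noise = noise)
  # displaced by exactly 3 points: shift of +/-3 brings it back
  sp <- to_frequency_domain(shifted_water(3))
  out <- align(sp, spc)
  expect_equal(abs(attr(out, "applied_shift")), 3)
  t_idx <- which.min(abs(out$axis - 4.7))
  expect_equal(which.max(Mod(out$intensities)), t_idx)
  # already aligned: zero shift, data unchanged
  sp0 <- to_frequency_domain(shifted_water(0))
  out0 <- align(sp0, spc)
  expect_identical(attr(out0, "applied_shift"), 0L)
  expect_identical(out0$intensities, sp0$intensities)
  # displaced beyond the search radius: correction saturates at 10
  sp15 <- to_frequency_domain(shifted_water(15))
  out15 <- align(sp15, spc)
  expect_lte(abs(attr(out15, "applied_shift")), 10)
})

test_that("alignment never corrects by more than 10 points", {
  noise <- ppm_range(-1, -3)
  spc <- alignment_spec(peaks = 4.7, noise = noise)
  for (d in -20:20) {
    out <- align(to_frequency_domain(shifted_water(d, n = 256)), spc)
    expect_lte(abs(attr(out, "applied_shift")), 10)
  }
})

test_that("alignment picks the candidate peak with the highest SNR", {
  p <- proton_params(512)
  step <- p$sweep_width / (p$transmitter_frequency * 512)
  # strong peak near 2.01 displaced by 2 points; weak peak near 3.03 aligned
  fid <- gen_fid(peak_model(ppm = c(2.01 + 2 * step, 3.03),
                            amplitude = c(10, 1), damping = 10),
                 p, noise_sd = 0.01, seed = 7)
  sp <- to_frequency_domain(fid)
  out <- align(sp, alignment_spec(peaks = c(3.03, 2.01),
                                  noise = ppm_range(-1, -3)))
  expect_equal(abs(attr(out, "applied_shift")), 2)
})

test_that("output range crops to the in-range points only", {
  sp <- random_spectrum(256, seed = 6)
  full <- ppm_range(max(sp$axis) + 1e-6, min(sp$axis) - 1e-6)
  expect_identical(output_range(sp, full)$intensities, sp$intensities)
  r <- ppm_range(5.0, 1.0)
  out <- output_range(sp, r)
  idx <- which(sp$axis >= 1.0 & sp$axis <= 5.0)
  expect_identical(out$intensities, sp$intensities[idx])
  expect_equal(out$axis, sp$axis[idx], tolerance = 1e-12)
  expect_error(output_range(sp, ppm_range(60, 59)),
               class = "mrs_parameter_error")
})

test_that("same Step V target and output range give equal lengths across spans", {
  # equal point counts, slightly different sweep widths
  p1 <- proton_params(1024, sw = 1000)
  p2 <- proton_params(1024, sw = 1080)
  w <- ppm_range(7.1, -2.7)
  crop <- function(p) {
    sp <- to_frequency_domain(gen_brain_like_sv(p, seed = 2))
    output_range(change_points_in_range(sp, 256, w), w)
  }
  o1 <- crop(p1); o2 <- crop(p2)
  expect_identical(length(o1$intensities), length(o2$intensities))
  expect_identical(length(o1$intensities), 256L)
})

test_that("every operator appends exactly one reproducible step record", {
  p <- proton_params(512)
  fid <- gen_brain_like_sv(p, seed = 31)
  sp <- to_frequency_domain(fid)
  sp1 <- set_reference(sp, 4.75)
  sp2 <- baseline_correct(sp1, ppm_range(-1, -3))
  sp3 <- l2_normalize(sp2)
  expect_identical(step_ids(sp3),
                   c("SetReference", "BaselineCorrection", "Normalization"))
  # replaying the recorded steps on the same input is bit-identical
  replayed <- replay_steps(sp, provenance_steps(sp3))
  expect_identical(replayed$intensities, sp3$intensities)
  expect_identical(replayed$axis, sp3$axis)
})

test_that("the pipeline runs steps in fixed order with domain conversions", {
  p <- proton_params(1024)
  fid <- gen_brain_like_sv(p, seed = 12)
  info <- additional_info("Tester", "Lab")
  # all steps disabled: plain transform, provenance holds no steps
  blank <- run_pipeline(fid, config_template(), info)
  expect_length(blank$preprocessing$steps, 0)
  expect_equal(blank$payload$spectrum$intensities,
               to_frequency_domain(fid)$intensities)
  # full configuration exercises every operator in order
  cfg <- config_template()
  cfg$set_reference <- list(enabled = TRUE, reference = 4.75)
  cfg$apodize <- list(enabled = TRUE, shape = "Lorentzian", linewidth = 2)
  cfg$water_filter <- list(enabled = TRUE, n_lorentzians = 5,
                           regions = list(ppm_range(5.25, 4.25)))
  cfg$baseline <- list(enabled = TRUE, regions = list(ppm_range(-1, -3)))
  cfg$change_points <- list(enabled = TRUE, target_points = 256L,
                            range = ppm_range(7.1, -2.7))
  cfg$set_to_zero <- list(enabled = TRUE,
                          intervals = list(ppm_range(12, 11)))
  cfg$normalization <- list(enabled = TRUE)
  cfg$alignment <- list(enabled = TRUE, peaks = c(2.01, 3.03),
                        noise = ppm_range(-1, -3),
                        brain_1p5T_preset = FALSE)
  cfg$output_range <- list(enabled = TRUE, range = ppm_range(7.1, -2.7))
  ds <- run_pipeline(fid, cfg, info)
  expect_identical(
    vapply(ds$preprocessing$steps, `[[`, character(1), "step_id"),
    c("SetReference", "Apodize", "WaterFiltering", "BaselineCorrection",
      "ChangePoints", "SetToZero", "Normalization", "AlignmentCorrection",
      "OutputRange")
  )
  expect_identical(length(ds$payload$spectrum$intensities), 256L)
  # replay of the full provenance is bit-identical
  replayed <- replay_steps(to_frequency_domain(fid), ds$preprocessing$steps)
  expect_identical(replayed$intensities, ds$payload$spectrum$intensities)
})

test_that("the canonical template produces the 512-point canonical vector", {
  p <- proton_params(2048)
  fid <- gen_brain_like_sv(p, seed = 42, noise_sd = 0)
  ds <- run_pipeline(fid, interpret_template(), additional_info("T", "L"))
  sp <- ds$payload$spectrum
  expect_identical(length(sp$intensities), 512L)
  expect_equal(sp$axis[1], 7.1, tolerance = 1e-9)
  # exactly unit norm right after the normalization step
  steps <- ds$preprocessing$steps
  upto_norm <- steps[seq_len(which(
    vapply(steps, `[[`, character(1), "step_id") == "Normalization"
  ))]
  at_norm <- replay_steps(to_frequency_domain(fid), upto_norm)
  expect_equal(sum(Mod(at_norm$intensities)^2), 1, tolerance = 1e-12)
  # the subsequent alignment shift can carry at most a few near-zero
  # edge points out of the cropped window
  expect_equal(sum(Mod(sp$intensities)^2), 1, tolerance = 1e-3)
})

test_that("a grid is processed uniformly, voxel errors are annotated", {
  p <- proton_params(512)
  g <- gen_mv_grid(2, 2, p, seed = 77)
  cfg <- interpret_template()
  cfg$change_points$target_points <- 128L
  info <- additional_info("T", "L", include_snr = TRUE)
  ds <- run_pipeline(g, cfg, info)
  expect_identical(ds$kind, "MV")
  lens <- vapply(ds$payload$voxels,
                 function(v) length(v$spectrum$intensities), integer(1))
  expect_true(all(lens == 128L))
  ax1 <- ds$payload$voxels[[1]]$spectrum$axis
  for (v in ds$payload$voxels) expect_equal(v$spectrum$axis, ax1)
  expect_true(all(vapply(ds$payload$voxels,
                         function(v) !is.null(v$snr), logical(1))))
  # a 1x1 grid stays a grid
  g1 <- gen_mv_grid(1, 1, p, seed = 3)
  ds1 <- run_pipeline(g1, cfg, info)
  expect_identical(ds1$kind, "MV")
  # operator failures carry the voxel position
  bad <- config_template()
  bad$baseline <- list(enabled = TRUE, regions = list(ppm_range(90, 89)))
  err <- tryCatch(run_pipeline(g, bad, additional_info("T", "L")),
                  mrs_error = identity)
  expect_match(conditionMessage(err), "voxel \\[row 1, col 1\\]")
})

test_that("work grows linearly with voxel count", {
  p <- proton_params(128)
  cfg <- config_template()
  cfg$normalization <- list(enabled = TRUE)
  cfg$set_reference <- list(enabled = TRUE, reference = 4.75)
  info <- additional_info("T", "L")
  reset_op_count()
  invisible(run_pipeline(gen_mv_grid(2, 2, p, seed = 1), cfg, info))
  ops4 <- op_count()
  reset_op_count()
  invisible(run_pipeline(gen_mv_grid(4, 2, p, seed = 1), cfg, info))
  ops8 <- op_count()
  expect_identical(ops8, 2L * ops4)
})
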