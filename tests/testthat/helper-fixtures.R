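# Shared fixtures: a 1.5 T proton-like acquisition whose span covers
# the canonical 7.1 to -2.7 ppm window, and small helpers used across
# test files.

proton_params <- function(n = 2048, sw = 1000, f0 = 63.86, ref = 4.7) {
  acquisition_params(f0, sw, n, reference_ppm = ref)
}

# A seeded random complex spectrum for brute-force oracle checks.
random_spectrum <- function(n = 256, seed = 1, params = proton_params(n)) {
  set.seed(seed)
  x <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
  spectrum(x, params)
}

# Water-only FID generated exactly on the carrier frequency.
water_on_carrier <- function(params = proton_params(512)) {
  gen_fid(peak_model(ppm = params$reference_ppm, amplitude = 10, damping = 10),
          params, noise_sd = 0)
}

step_ids <- function(x) {
  vapply(provenance_steps(x), `[[`, character(1), "step_id")
}

expect_dataset_equal <- function(a, b, tol = 1e-12) {
  expect_identical(a$kind, b$kind)
  av <- if (a$kind == "SV") list(a$payload) else a$payload$voxels
  bv <- if (b$kind == "SV") list(b$payload) else b$payload$voxels
  expect_length(bv, length(av))
  for (i in seq_along(av)) {
    expect_equal(bv[[i]]$spectrum$intensities, av[[i]]$spectrum$intensities,
                 tolerance = tol)
    expect_equal(bv[[i]]$spectrum$axis, av[[i]]$spectrum$axis, tolerance = tol)
    expect_identical(bv[[i]]$label, av[[i]]$label)
    expect_identical(is.null(bv[[i]]$snr), is.null(av[[i]]$snr))
    if (!is.null(av[[i]]$snr)) {
      expect_equal(bv[[i]]$snr$snr, av[[i]]$snr$snr, tolerance = tol)
    }
  }
  sa <- a$preprocessing$steps
  sb <- b$preprocessing$steps
  expect_identical(vapply(sb, `[[`, character(1), "step_id"),
                   vapply(sa, `[[`, character(1), "step_id"))
  ia <- a$preprocessing$additional_info
  ib <- b$preprocessing$additional_info
  expect_identical(ib$name, ia$name)
  expect_identical(ib$place, ia$place)
  expect_identical(ib$label, ia$label)
  expect_identical(ib$keywords, ia$keywords)
  expect_identical(ib$meta_data, ia$meta_data)
}
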