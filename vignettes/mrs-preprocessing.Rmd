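---
title: "Harmonizing MRS spectra: the preprocessing pipeline and its exchange format"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing MRS spectra: the preprocessing pipeline and its exchange format}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsxml)
```

## The problem

In-vivo magnetic resonance spectroscopy (MRS) measures the chemical
composition of a tissue volume (voxel) non-invasively. Pattern-recognition
analyses that pool spectra from several scanners need every spectrum on the
same footing: the same number of points over the same chemical-shift (ppm)
window, comparable intensity scale, residual water removed, and peaks sitting
at their theoretical positions. Just as importantly, a classifier trained on
such data is only trustworthy if every input demonstrably went through the
*same* preprocessing — so the processing history has to travel with the data.

`mrsxml` addresses both halves: an ordered pipeline of preprocessing
operators for single-voxel (SV) spectra and multi-voxel (MV) grids, and a
self-descriptive XML exchange format that stores the processed spectra
together with a complete, replayable provenance record. Because the format
admits only a fixed vocabulary of elements (the validator rejects anything
else), there is no sanctioned place for patient identifiers: exported files
are anonymized by construction.

## The signal model and axis conventions

A raw acquisition is a free-induction decay (FID): `n` complex samples at
dwell time `1/sweep_width`. The package models it, where a model is needed,
as a sum of exponentially damped complex sinusoids

$$ s_t \;=\; \sum_j a_j\, e^{i\phi_j}\, e^{(\,i 2\pi f_j - d_j)\,t} + \varepsilon_t , $$

with amplitude $a_j$, phase $\phi_j$, baseband frequency $f_j$ (Hz, signed
offset from the carrier), damping $d_j$ (s$^{-1}$; a Lorentzian line of full
width at half maximum $d_j/\pi$ Hz), and circular complex Gaussian noise
$\varepsilon_t$.

The ppm axis follows the MRS display convention: strictly decreasing, high
ppm on the left. Index $k$ (0-based) maps to
`reference_ppm + (floor(n/2) - k) * sweep_width / (transmitter_frequency * n)`,
so the carrier sits at the centre bin and carries exactly `reference_ppm`.
The forward DFT is unscaled, the inverse carries $1/n$, and the transform
output is rotated so index 1 is the highest ppm; a resonance at baseband
frequency $f$ therefore appears at `reference_ppm + f / transmitter_frequency`.
The same conversion is used everywhere a ppm value has to be turned into a
frequency (synthetic generation, HLSVD region selection, alignment), so a
peak is always selected where it actually appears.

## The pipeline

Steps always execute in fixed order, lowest first; each operator appends one
provenance record holding exactly its inputs.

| Step | Operator | Domain | Parameters (units) |
|------|----------|--------|--------------------|
| I    | `set_reference()` | freq | new carrier reference (ppm) |
| II   | `apodize()` | time | shape, linewidth (Hz) |
| III  | `hlsvd_filter()` | time | number of Lorentzians, up to 3 regions (ppm) |
| IV   | `baseline_correct()` | freq | up to 3 reference regions (ppm) |
| V    | `change_points_in_range()` | both | target point count, range (ppm) |
| VI   | `set_to_zero()` | freq | up to 2 intervals (ppm) |
| VII  | `l2_normalize()` | freq | none |
| VIII | `align()` | freq | theoretical peaks (ppm), noise region |
| IX   | `output_range()` | freq | exported window (ppm) |

Design notes on the individually less obvious operators:

* **Referencing (I)** only re-labels the axis; it does not move intensities.
  Whether referencing should also shift the data circularly is ambiguous;
  axis re-labelling is the conservative reading, and the alignment step
  (VIII) exists precisely to move data onto theoretical positions.
* **Apodization (II)** uses the standard NMR windows: Lorentzian
  `exp(-pi * lw * t)` and Gaussian `exp(-(pi * lw * t)^2 / (4 ln 2))`; both add
  `lw` Hz to the FWHM of the matching line shape (verified against a measured
  FWHM oracle in the tests). `t = 0` is never attenuated.
* **Water filtering (III)** fits the FID with a rank-`k` HSVD subspace model:
  Hankel matrix of shape `floor(n/2) x (n - floor(n/2) + 1)` (near-square
  maximizes rank), truncated SVD, poles from the shift invariance of the
  dominant left-singular subspace by least squares, amplitudes by a final
  linear fit. "Number of Lorentzians" is the truncation rank; no automatic
  order selection is attempted. Components whose ppm position falls in any
  selected region (closed intervals) are reconstructed and subtracted.
* **Baseline (IV)** subtracts the *mean of per-region means* — not the pooled
  mean — which differs when regions hold unequal point counts; the nested
  rule is the documented behaviour.
* **Resampling (V)** guarantees an exact point count inside the requested
  range. With too few points the FID is zero-filled (doubling the length,
  FFT-friendly) until the range holds enough; with too many, a uniform
  target grid over the range (extended at the same spacing to the full
  original span) takes the *nearest original point* for each coordinate —
  literal undersampling by skipping values, no interpolation, ties to the
  higher-ppm neighbour. The output axis is the uniform target grid, which
  keeps the compact `(ppm_first, ppm_step, n)` serialization exact and puts
  the first canonical point exactly at the range's upper bound.
* **Alignment (VIII)** evaluates, for each theoretical peak, the SNR
  `max |x| / (2 * sd(noise))` with the peak search confined to ±10 points
  around the theoretical index, picks the best-scoring peak, and shifts the
  spectrum by the integer number of points (never more than 10 — a smaller
  ppm window at higher resolution) that puts that peak's local maximum on
  its theoretical index. The shift is circular with the wrapped edge zeroed,
  so no data is invented. Noise SD is computed on the real part; the peak
  amplitude is the complex magnitude.

Numerical details: ppm ranges are closed intervals; membership tests use an
absolute guard of 1e-9 ppm, ten orders of magnitude below typical axis
spacings, to absorb floating-point error in axis construction. SNR raises a
dedicated error on a degenerate (constant) noise region, and normalization
on an all-zero spectrum.

## The canonical 512-point template

`interpret_template()` (also shipped as
`inst/extdata/interpret-template.xml`) reproduces the canonical
pattern-recognition layout: 512 points spanning 7.1 to −2.7 ppm, first point
at 7.1 ppm, unit-length spectra, alignment enabled. Two choices in it are
the package's own:

* Because normalization (VII) always precedes the output crop (IX), spectral
  energy outside the canonical window would leave the exported vector with
  norm below 1. The template therefore zeroes the tails outside
  [−2.7, 7.1] ppm (step VI) before normalizing — the use the zeroing step is
  designed for. The exported vector then has unit norm exactly, up to the
  few near-zero edge points an alignment shift can carry out of the window
  (at most 10, typically a loss below 1e-4 in squared norm).
* The alignment peak list holds the major proton-brain singlets — choline
  (3.21 ppm), creatine (3.03 ppm), N-acetylaspartate (2.01 ppm) — with the
  noise region in the signal-free upfield tail [−2.7, −0.7] ppm. The 1.5 T
  brain preset of the original alignment procedure is not published as a
  table, so it is deliberately not hard-coded: `brain_1p5T_preset` marks
  provenance, and the positions are loaded from a site-maintained file via
  `load_peak_list()`.

## Provenance and the exchange format

A `Dataset` pairs one provenance record with exactly one payload (one voxel,
or one m×n grid — a 1×1 grid stays a grid). Step elements serialize in
pipeline order; the absence of a step element means the step was not
performed; only `AdditionalInformation` with non-empty `Name` and `Place` is
always required (minimum traceability of who processed the data, and where).
Keywords are capped at 45 characters; the free `MetaData` text is stored
verbatim as an observation notebook. Grid voxels carry axis-named position
attributes — column maps to `Xaxis`, row to `Yaxis`, with the top-left voxel
at [1, 1] — and `Zaxis` is always 1 (single-slice processing; the attribute
exists for future multi-slice data). Intensities are stored as alternating
real/imaginary pairs at 17 significant digits, which round-trips doubles
exactly; the axis is stored as `(ppm_first, ppm_step, n)` under the
uniform-grid invariant rather than as a full vector.

Because operators record exactly their inputs, `replay_steps()` on the same
raw input reproduces a pipeline's output bit for bit — the tests assert
this, and it is what makes the provenance an audit record rather than
documentation.

## The synthetic generator

Real MRS acquisitions are not redistributable here, so fixtures are
generated: sums of damped complex sinusoids at typical proton-brain
positions (dominant residual water at 4.7 ppm; choline 3.21, creatine 3.03,
N-acetylaspartate 2.01, lactate 1.33 ppm) with i.i.d. circular complex
Gaussian noise per quadrature channel (`noise_sd = 0.05` against a water
amplitude of 50 — a clearly water-dominated, low-noise regime typical of
unsuppressed acquisitions). The default acquisition emulates 1.5 T proton
conditions: 63.86 MHz transmitter, 1000 Hz sweep width (15.66 ppm, covering
the canonical window), reference 4.7 ppm. Generators are pure functions of
their parameters and a seed, and always return their ground truth (peak
tables, grid masks) so tests never re-derive it.

What the generator does *not* emulate: J-coupled multiplets, macromolecular
baselines, eddy-current or phase distortions, lineshape deviations from
Lorentzian, and spatial noise correlations in grids. Passing tests therefore
demonstrate the operators' contracts — not clinical-grade robustness on
pathological in-vivo data.

Problem sizes used in the tests and acceptance checks are desk-scale by
choice: 256–2048 points for single spectra (one 32768-point spectrum for
the apodization FWHM oracle), grids up to 16×16 with 64–1024 points per
voxel; the full suite runs in a few seconds.

## Known limitations

* Zero/first-order phasing, frequency-domain filtering and eddy-current
  correction are out of scope; the `MetaData` notebook is the place to
  record that they were applied elsewhere.
* Baseline correction assumes a non-sloped baseline by design.
* The undersampling rule preserves raw values at the cost of up to half a
  source-grid bin of positional jitter per point; peak positions stay
  within one output-grid bin (asserted by tests).
* Multi-slice (3-D) grids are not processed; `Zaxis` is stored but fixed
  at 1.
* Vendor raw formats and DICOM are not read; the exchange format itself
  (or the synthetic generator) is the entry point.
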