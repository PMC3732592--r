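---
title: "Models and methods behind mrsikit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mrsikit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsikit)
```

# The problem

Magnetic resonance spectroscopic imaging (MRSI) acquires a free induction
decay (FID) — a complex time-domain signal — at every position of a 3-D
voxel grid, often through multiple receive channels, so a dataset is at
least five-dimensional: `(x, y, z, spectral, channel)`. Unlike anatomical
MRI, this data usually leaves the scanner in proprietary raw formats and
must be reconstructed, processed, quantified, and rendered offline before a
radiologist can use it. `mrsikit` implements that workflow end to end in R:
a reader/mapper architecture that isolates acquisition-specific detail from
a vendor-neutral data model, a reconstruction chain, HSVD water/baseline
removal, metabolite quantification, and DICOM encoders for every product so
the results can live in a standard clinical archive alongside the rest of
the exam.

# Data model and conventions

All processing operates on an `mrs_dataset`: a complex 5-D array plus a
`spectral_axis` (points `N`, dwell time `dt`, sweep width `SW = 1/dt`,
transmitter frequency `f0` in MHz, `ppm_ref`), an `mrs_geometry` (origin,
spacing, direction cosines, dims — DICOM conventions: LPS patient
coordinates, 0-based voxel indices, voxel-center addressing), per-axis
spatial domain flags (k-space vs image), the selection box and sat-band
annotations, and a provenance trail in which **every operation appends
exactly one record** and never mutates its input.

Fixed transform conventions (every other choice in the package follows
from these):

* Forward DFTs are unscaled sums; inverse DFTs carry the full `1/N`. Hence
  Parseval reads `sum |image|^2 * N_spatial = sum |kspace|^2`.
* Centred layouts come from `fftshift` after a forward transform and
  `ifftshift` before an inverse one. The spectral carrier (0 Hz offset)
  sits at index `floor(N/2)`.
* Chemical shift decreases as the spectral index increases (the NMR
  display convention):
  `ppm(i) = ppm_ref + (floor(N/2) - i) * SW / (N * f0)`.
* `ppm_ref` defaults to 4.7 ppm, water at body temperature, the standard
  in vivo 1H reference when a source format does not say otherwise.

# The synthetic phantom

`generate_phantom()` is first-class, tested code: it emulates the raw
multi-voxel, multi-channel time-domain acquisition a scanner would
produce, with known ground truth. Each voxel FID is a sum of damped
complex exponentials

$$x[n] = \sum_m a_m e^{i\phi_m} e^{(i 2\pi f_m - \pi d_m)\, n\, \Delta t},
\qquad f_m = (\mathrm{ppm}_{ref} - \mathrm{ppm}_m) f_0 ,$$

with `d_m` parameterized as the Lorentzian FWHM in Hz (time-domain decay
`pi * d`), which keeps apodization and quantification checks analytic.
Voxel signals are scaled per ellipsoidal region, multiplied by coil
sensitivities (smooth in-plane Gaussians plus a constant floor, one
distinct global phase per channel — deliberately exercising the phase
invariance of sum-of-squares combination), forward-DFT'd per spectral
sample into k-space, optionally delay-shifted and reordered for an
echo-planar (EPSI) readout, and finally perturbed with i.i.d. complex
Gaussian noise (`noise_sigma` is the standard deviation of the real and of
the imaginary part of each k-space sample). One integer seed drives the
single noise generator; identical configuration and seed give
byte-identical files.

Default conditions (chosen once, as a realistic quality-assurance phantom
scan, and calibrated so the designed pipeline contract below holds):
16×16×4 grid of 10 mm voxels, 512 spectral points at `SW` 1000 Hz,
`f0` 127.7 MHz (3 T 1H), single channel. Metabolites at textbook shifts —
NAA 2.01, Cr 3.03, Cho 3.22, water 4.70 ppm — with 2 Hz linewidths for the
metabolites (a well-shimmed solution phantom) and 5 Hz for water.
Amplitudes are NAA 1.0, Cr 0.6, Cho 1.0 (region-scaled), and water 8.0,
modelling the *residual* after water suppression; simulating an
unsuppressed acquisition just means raising the water amplitude (roughly
1000× the metabolites in vivo), which is what the water-removal tests do.
Two ellipsoidal regions fix the headline ground truth: "normal" with
Cho:NAA amplitude ratio 0.5 and "tumor-like" with 2.0.

What the generator does **not** emulate — so what passing tests do *not*
show about real data: eddy-current and B0-inhomogeneity lineshape
distortions, macromolecule baselines, J-coupled multiplets, subject motion,
spatially varying frequency drift, and the amplitude-envelope skew of real
EPSI readouts (next section). Recovery numbers on the phantom are
best-case; on in vivo data the quantification windows and the HSVD model
order would need tuning against those effects.

# Reconstruction chain

* **Apodization** multiplies each FID by `exp(-pi * L * t)` (Lorentzian,
  adds exactly `L` Hz of Lorentzian width) or
  `exp(-(pi * L * t)^2 / (4 ln 2))` (Gaussian of spectral FWHM `L`).
* **Zero filling** extends FIDs with zeros; `SW` and dwell are unchanged,
  and the interpolated spectrum agrees with the original at the original
  bin centres exactly (a DFT identity the tests assert).
* **Spatial reconstruction** is the centred inverse DFT per spectral
  sample and channel; it inverts the phantom's forward model to machine
  precision in memory, and to ~5e-8 relative through a raw file (the raw
  container stores complex64; processing is double precision throughout).
* **Spectral FFT** offers optional *first-point half-scaling*. A truncated
  one-sided decaying exponential leaves a constant offset of half the
  first sample in the real spectrum across all bins; with several
  components (water especially) that baseline biases window-maximum peak
  heights by several percent. Halving `x[0]` before the transform removes
  it exactly for this signal class. The flag is off by default —
  `spectral_ifft()` is the exact inverse only of the unflagged transform —
  and enabled in the quantification pipelines.
* **EPSI delay correction.** An echo-planar readout samples k-step `k`
  along the readout axis at times shifted by `k * tau`. The generator
  models this delay as the exact frequency-proportional phase ramp
  `exp(+i 2 pi f k tau)` (a circular time shift — the first-order
  linear-phase model of the delay), and `epsi_phase_correct()` applies the
  conjugate ramp, so the pair is exactly unitary and a corrected EPSI
  acquisition matches its cartesian twin to float32 precision. Real EPSI
  also skews the decay envelope by `exp(-pi d k tau)`, which no
  phase-only correction can undo; that envelope effect is deliberately
  outside the model. When `tau * SW * k_max >= 1` the correction is in the
  wraparound regime and a warning is recorded in provenance.
* **Coil combination** is pointwise sum-of-squares,
  `sqrt(sum_c |v_c|^2)`, in whatever domain the data occupies. It is
  invariant to per-channel phase rotations and discards phase (the output
  is flagged magnitude-only in provenance), so phase-sensitive steps must
  run first.
* **Phasing**: `S'[i] = S[i] exp(i (phi0 + phi1 (i - pivot)/N))`, with the
  first-order term in radians across the full width about an explicit
  pivot bin (the common spectroscopist control; `phi1 = 0` at the pivot
  makes the identity case testable). `auto_phase0()` maximizes the summed
  real part over a ppm window by a 1-degree grid search plus
  golden-section refinement to 0.01 degree; it recovers a simulated
  zero-order phase exactly on a symmetric window around an on-grid
  singlet, and is amplitude-scale invariant. It fits no first-order term.

The designed end-to-end contract: on the noiseless default phantom, the
pipeline apodize(L = 4 Hz) → zero-fill ×2 → spatial recon → spectral FFT
(first-point halved) → phase → peak-height quantification recovers the
region-wise Cho:NAA ratios within 2% (measured: 0.8–0.9%); at spectral
SNR ≈ 20 on the NAA peak, within 10%. The residual noiseless error is
dominated by the Cr tail under the Cho window plus off-grid bin sampling
of the sharp lines, effects that partially cancel at the default
linewidths.

# HSVD

`hsvd_fit()` decomposes an FID into damped complex exponentials: build the
`L × (N - L + 1)` Hankel matrix `H[i, j] = x[i + j]` with `L = floor(N/2)`
(near-square, the standard conditioning choice), truncate the SVD to the
top `K` left singular vectors (default `K = 25`, typical for in vivo 1H
water-plus-metabolite modelling), solve the shift-invariance relation
between the top and bottom row blocks via the pseudo-inverse, and take the
eigenvalues `z_k` of the resulting `K × K` matrix (complex, non-symmetric —
complex eigenvalues are expected and kept): frequency
`Arg(z_k) / (2 pi dt)`, damping `-log|z_k| / dt`. Amplitudes and phases
come from a linear least-squares fit of `x[n]` on `z_k^n`; a
rank-deficient solve falls back to the minimum-norm solution with a
warning. Growing components (`|z| > 1`) are discarded by default before
subtraction to avoid amplifying noise. Components below
`1e-12 * max|x|` are dropped.

`hsvd_filter()` fits each voxel and subtracts the model signal of every
component whose frequency falls inside a ppm band — canonically
4.2–5.2 ppm for residual water. On noiseless signals within the model
class the fit is exact to near machine precision, so removal clears
>99.9999% of the band energy while perturbing the NAA window area at the
1e-10 level relative to a water-free reference.

# Quantification

Peak height is the maximum of the real part (or magnitude, for
combined/unphased data) over a window's bins; integrated area is the
Riemann sum times the bin width in Hz — in these units the analytic
absorption-mode total of an amplitude-`a` Lorentzian is `a * SW / 2`.
Default windows: Cho 3.12–3.32, Cr 2.93–3.13, NAA 1.91–2.11 ppm. The noise
map is the per-voxel standard deviation of the real part over a
signal-free region (default 6.5–8.0 ppm), and the ratio map divides two
maps wherever the denominator exceeds `k_mask = 4` noise standard
deviations, masking everything else — voxels outside the excitation volume
come out masked by construction. The Cho/NAA product is labelled
`cho_naa_index`; it is a plain masked ratio of peak heights, not the
regression-based index used in the clinical literature, and the two should
not be compared numerically. Maps export as DICOM Enhanced MR Image
instances and as NIfTI.

# DICOM encoding

Only Explicit VR Little Endian is written (and read back), for maximal
interoperability and byte-stable golden files. Four SOP classes cover the
workflow: MR Spectroscopy (`…4.2`), Raw Data (`…66`) with per-file SHA1
digests verified on extraction, Enhanced MR Image (`…4.1`) with 16-bit
rescale-slope/intercept quantization (error bounded by one step of
`(max - min)/65535`), and Secondary Capture (`…7`) for report rasters.
Spectral payloads are 32-bit float interleaved real/imaginary in
(5600,0020), ordered frame → row → column → point. Geometry travels in
per-frame plane positions; the selection box is encoded as the first three
items of the Volume Localization Sequence (one slab per axis) with sat
bands as further items. Raw payloads and the metabolite-map mask live in a
documented private block (creator `"MRSIKIT RAW 1.0"`, group 0x7777).
UIDs are derived deterministically from content hashes under the 2.25
root, and dates are fixed constants, so identical inputs produce
byte-identical DICOM files — the reproducibility contract extends to the
archive products. Inbound dialects the reader does not understand
(multi-channel MRS instances, other transfer syntaxes) are rejected, not
guessed. Decimal-string attributes round-trip at 10 significant digits;
full-precision copies of quantization parameters ride in the private
block.

# Rendering

Report panels are rasterized in pure R integer arithmetic — no graphics
device, no fonts — so identical inputs give byte-identical 1024×1024 RGB
rasters: anatomical grayscale underlay (nearest-neighbour resample),
semi-transparent heat-ramp metabolite overlay in unmasked voxels, voxel
grid, one real-part spectrum polyline per voxel, the selection box outline
in pure yellow, and purple sat-band shading. `build_report()` emits one
panel per requested slice plus two summary panels, encoded as one
Secondary Capture series (with optional PNG copies).

# Problem sizes and numerical tolerances used by the tests

The suite runs the full default phantom (16×16×4 × 512 points) for the
end-to-end, transform-identity, and determinism checks, and 8×8×2 × 256
phantoms elsewhere; HSVD oracles use 256-point single-voxel FIDs with a
Levenberg-Marquardt refit (initialized at truth) as the independent
reference. Float32 file precision bounds raw-file round trips at ~1e-6
relative; in-memory identities are asserted at 1e-9 to 1e-12; HSVD
parameter recovery at 1e-6. An independent DICOM implementation (pydicom)
must open every written file.

# Known limitations

Axis-aligned processing only (oblique direction cosines are stored and
round-tripped, never resampled); no gridding for non-Cartesian
trajectories; no SENSE-style coil combination; no B0/frequency-drift
correction; no model-based basis fitting (LCModel-style) or absolute
concentration scaling; plain HSVD (no Lanczos acceleration), so
whole-volume filtering at high model order is slow; DICOM support covers
the attribute set above, not full IOD conformance, and no network
transport (files are the interface to the archive).
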