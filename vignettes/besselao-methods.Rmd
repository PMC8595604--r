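---
title: "Models and methods behind besselao"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind besselao}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`besselao` simulates focal-plane adaptive optics (AO) for Bessel-focus
two-photon microscopy. This vignette records the physical model, the
conventions the package fixes where the field uses several, the design
choices that were genuinely open, and the limits of what the simulations
can show. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The optical model

### Pupil sampling and propagation

The objective back pupil is sampled on an even `grid_n` × `grid_n`
Cartesian grid in numerical-aperture (NA) units, centred so the zero
coordinate falls on index `grid_n/2 + 1`. The grid edge sits at
`pupil_oversampling × na_objective`; with the default oversampling of 2
the pupil disk spans half the grid, which zero-pads the discrete Fourier
transform and fixes the focal-plane pixel pitch at
`wavelength / (2 × pupil_oversampling × na_objective)` — 0.224 µm for the
default 940 nm / 1.05 NA / 2× configuration. `propagate()` is a centred,
unitary FFT: energy is conserved exactly, forward-then-inverse is the
identity to machine precision, and applying the forward transform twice
is a parity flip. These are tested properties, and they matter because
the correction pipeline leans on exact round trips.

The defaults describe the instrument modelled throughout: a 940-nm
excitation laser, a 25×/1.05-NA water-dipping objective (n = 1.33)
behind a 200-mm tube lens (pupil radius 8.4 mm; the tube focal length is
the package's assumption — Nikon's standard — since only the
magnification is printed on an objective), and a transmissive annular
mask of 1.015/1.2 mm diameters relayed to the pupil by lens pairs
750→350, 30→30, 30→150, 120→240 mm (magnification 14/3). Mapping the
mask through that chain gives an annulus of NA 0.296–0.350, nominally
called a "0.4-NA" Bessel focus; both the hardware-derived
(`annular_mask()`) and nominal (`annular_mask_na()`, `thin_annulus()`)
parameterizations are supported, and the package reports the
hardware-derived numbers rather than resolving the discrepancy.

### Focusing: scalar Debye with sine-condition apodization

`compute_psf()` and `axial_profile()` use the scalar Debye model: each
pupil sample is weighted by the aplanatic factor `(1 − (NA/n)²)^(−1/4)`
(the sine condition expressed in pupil coordinates — on a Cartesian pupil
grid the solid-angle Jacobian folds into the apodization, turning the
familiar `√cosθ` into `1/√cosθ`), multiplied by the defocus kernel
`exp(i k z √(n² − NA²))`, and Fourier transformed; the one-photon
intensity is `|U|²` and the two-photon excitation signal is `|U|⁴` by
construction. Polarization is neglected. At 1.05 NA this costs a few
percent of axial accuracy: the model gives a two-photon axial FWHM of
1.17 µm for the full pupil where a vectorial calculation and the
instrument it models land nearer 1.08 µm, a ~8% offset that is inside
every comparison tolerance used here, and the package's comparisons are
deliberately ratio-based where possible. The hardware annulus gives
44.3 µm (measured instruments report ≈43 µm). On-axis axial profiles
never need a transform — the DC sample of the FFT is the plain pixel sum
— so `axial_profile()` evaluates them directly and fast.

One consequence worth recording: the through-centre axial FWHM of a 2-µm
uniformly fluorescent sphere imaged by this diffraction-limited Gaussian
PSF converges to ≈2.1 µm (a 2-µm top-hat convolved with a 1.17-µm
two-photon axial profile cannot be much wider). Published bead
measurements through cranial windows run ≈2.6 µm; the gap is consistent
with micrometre-scale z-stepping and residual aberration in a real
measurement and is not reproducible by an ideal-model calculation — the
package reports its own converged number.

### Zernike conventions

Published SLM aberration work uses several Zernike normalizations, so
the package fixes one and documents it prominently:

* **Born–Wolf (unnormalized) polynomials.** Radial part with
  `R_n^|m|(1) = 1`, azimuthal factor `cos(mθ)` for m > 0, `sin(|m|θ)`
  for m < 0, 1 for m = 0. An amplitude of "1 wave" means the
  polynomial's *peak value* on its unit disk is one wavelength of path
  difference (so defocus spans −1…+1 waves across the disk). This is the
  common SLM-control convention and makes "1 wave" reproducible.
* **Ordering.** Modes sort by radial order n, then by m ascending; the
  "first 55 modes" are exactly radial orders 0–9.
* **Phase wrap.** Phases are stored wrapped to (−π, π]; 8-bit SLM export
  maps [0, 2π) linearly onto levels 0–255.

`fit_zernike()` is a plain least-squares projection on the pixelated
disk. The pixelated edge limits mode–mode orthogonality to ~10⁻² at
grid 256; with edge-coverage-weighted quadrature (supersampled partial
pixels, used by the orthogonality tests) the basis is orthogonal to
better than 10⁻³. For fitting this distinction is immaterial because the
projection and the reconstruction share the same sampled basis.

### The corrective-pattern pipeline

`compute_focal_correction()` follows a fixed order: truncate the
measured wavefront to the pupil disk → fit 55 modes → zero tip, tilt and
defocus → rebuild the smooth wavefront → impose the annular amplitude →
forward-propagate → keep only the phase. Fitting *before* masking
matters because measured pupil-segmentation wavefronts are piecewise
flat with discontinuous gradients; transforming them raw would imprint
artifacts. Tip/tilt must go because they would walk the ring
illumination off the physical mask; defocus must go because it skews the
axial profile. The phase-only step (the SLM cannot shape amplitude) is
an approximation whose quality is exactly what `validate_focal_pattern()`
measures: back-propagate `exp(i·pattern)` with uniform amplitude and
report (a) the fraction of pupil energy landing inside the ring,
normalized by the same fraction for the zero-aberration pattern, and
(b) the intensity-weighted circular phase agreement
`|Σ w e^{i(φ_rec − φ_exp)}| / Σ w` inside the ring, which is immune to a
global phase offset. Defaults flag patterns below 0.8 containment ratio
or 0.9 agreement; for smooth aberrations up to 1.5 waves RMS the
pipeline sits at ≥0.95 agreement in the test suite.

A model-level observation the tests also exercise: corrected Bessel
peaks can exceed the unaberrated reference slightly. The zero-aberration
pattern is the phase of a *real* focal field, i.e. a binary 0/π
hologram, which splits energy between conjugate orders; an aberrated
field's smoother kinoform couples into the annulus a little more
efficiently. The recovery criterion (≥90% of the unaberrated peak) is
unaffected.

## Aberration scaling for beam-sensitivity studies

How a "1-wave" test aberration affects the Bessel focus depends
critically on the aperture over which the mode is scaled — an open
convention the package must fix. Scaled to the full 1.05-NA pupil, the
thin ring at NA ≈ 0.3 samples astigmatism at ~0.15 of its peak, and the
annular focus would appear far *more* robust to astigmatism and trefoil
than the Gaussian focus, inverting the behaviour AO-corrected
instruments actually show. `mode_sensitivity_scan()` therefore scales
test modes to the annular illumination's footprint: the mode disk's edge
sits at √2 × the ring-centre NA, so the ring lies at the disk's RMS
radius ρ = 1/√2. That radius is also the stationary point of primary
spherical aberration (dR₄⁰/dρ = 0 at 1/√2), so on a thin ring m = 0
modes act as piston plus a mild axial shift, |m| = 1 modes act as pure
tilt (a translation), and only |m| ≥ 2 modes corrupt the azimuthal phase
— the analytic property of ideal Bessel beams. Under this shared
pattern the Gaussian focus crosses only the mode's central bump and
keeps 30–50% of its peak where the Bessel focus drops to 5–10%,
reproducing the characteristic ordering (astigmatism and trefoil hurt
Bessel more; coma and spherical barely touch it). The full-pupil
convention remains available via `na_scale`, and `aberrated_peak_ratio()`
defaults to it for general use. Peak ratios are searched over an axial
window (default ±2 axial FWHMs — note a full wave of defocus displaces
the 1.05-NA Gaussian focus by ≈4.5 µm, so defocus studies should pass a
wider `z_span`) and over the lateral plane with parabolic sub-pixel
refinement, so displacement never masquerades as loss.

## Wavefront sensing

`simulate_segment_images()` divides the pupil's bounding square into
5 × 5 tiles (corner tiles are kept when ≥25% of their area overlaps the
disk, weighted by that area), illuminates one tile at a time, and forms
the two-photon image of an isolated fluorescent bead (the bead enters as
its 2-D chord-length projection; sub-voxel beads as mass deposits).
Localization (`estimate_shifts()`) cross-correlates each tile image
against that *same tile's* unaberrated calibration image, with separable
parabolic sub-pixel refinement; a full-pupil reference image is also
produced but is not the default, because its shape differs from a
beamlet's and measurably biases the correlation peak. A centroid
localizer is available as the alternative.

The displacement ↔ gradient calibration is physical and shared by the
simulator and the reconstructor: a wavefront slope of g waves per NA
unit displaces the focus by `wavelength × g` micrometres (sign fixed by
the package's FFT conventions and verified by round trip).
`reconstruct_wavefront()` converts displacements to tile-mean gradients
and solves a weighted modal least-squares system. Tip and tilt columns
are *included* in the solve and zeroed afterwards — a uniform
displacement component must be absorbed by them, because higher-order
columns (coma in particular) have nonzero tile-averaged gradients and
would otherwise soak it up. Piston has no gradient signal and is never
in the system. The default reconstruction order (n ≤ 4, 14 modes) is
well-determined by 2 × 21 gradient equations; requesting more modes than
the valid tiles support reduces the order with one warning. The closed
loop (`ao_closed_loop()`) recovers ≥90% of the unaberrated Bessel peak
for random smooth aberrations up to 1.5 waves RMS, with reconstruction
residuals of a few hundredths of a wave in the noiseless case.

### Displaced aberrations and the pupil-vs-focal contrast

Sample aberrations arise inside tissue, not at the pupil.
`sample_screen()` + `apply_sample_screen()` place a thin smooth phase
screen at an axial distance from the focus (Debye propagation there and
back), which distorts both phase and amplitude of the annular field at
the pupil. `compare_correction_strategies()` senses the screen with a
full-pupil beam (valid while the distorted pupil phase stays within
about half a wave — no unwrapping is attempted; supply `w_meas` for
stronger screens) and compares no correction, phase-only pupil
correction, and the focal-plane pattern. A known limitation, recorded
here deliberately: within this single-thin-screen scalar model the
geometric (eikonal) regime lets *both* correction routes recover the
peak almost equally, and the package's tests assert only what the model
supports — that a displaced screen costs signal which either correction
largely restores, and that the focal pattern restores the annular
amplitude-plus-phase structure (the round-trip validation). The
experimentally observed *superiority* of focal-plane correction arises
from aberrations distributed near focal-conjugate planes of a real relay
and from sensing with a Gaussian beam while correcting a thin annular
one; reproducing it would need a multi-plane instrument model that is
out of scope.

## Synthetic specimens and imaging

`make_phantom()` renders beads (given or random positions/diameters) and
dendrite phantoms (a smooth random-walk tube, default radius 0.4 µm,
decorated with spherical spines of 0.5–1.5 µm diameter on short stems,
rejection-sampled against overlap) with one-voxel anti-aliased surfaces;
every object is catalogued. `image_phantom()` is FFT correlation with
the two-photon PSF — the scanning formulation, `image(r) = Σ ρ(r′)
PSF(r′ − r)` — producing either the plane-by-plane Gaussian stack or the
single-sweep Bessel projection (the mid-plane of the 3-D correlation
with the axially extended PSF); the object volume is compactly
supported, so plain zero padding is used (the circular wrap is
innocuous), while Richardson–Lucy deconvolution (`deconvolve()`)
renormalizes flux after its circular convolutions, preserves
nonnegativity, and returns the input unchanged at zero iterations.
Poisson noise is parameterized by expected photons at the brightest
pixel, always with an explicit seed. The "resolvable spine" criterion
for tests is a local maximum within 0.5 µm of a catalogued spine
exceeding the image median background by 2× (configurable) — a proxy for
the manual counting practitioners do.

## Functional statistics

Sessions follow the two published acquisition modes: 12 drifting-grating
directions (0–330° in 30° steps) in seeded pseudorandom order, epochs of
(2, 4, 2) s at 3.3 Hz for Gaussian scanning and (4, 6, 2) s at 1.5 Hz
for Bessel volumetric scanning. Choices the package fixes where usage
varies:

* **F₀ is per-trial** (mean over that trial's pre-stimulus blank), the
  drift-robust reading of "blank preceding the stimulus".
* **Transient thresholds**: ΔF/F₀ > 20% for calcium; glutamate
  thresholds of 10% or 5% both appear in practice, so the threshold is
  an argument (default 0.2 for calcium analyses; pass 0.10 or 0.05 for
  glutamate).
* **Selectivity** is one-way ANOVA across the 12 directions at p < 0.05,
  with degenerate inputs handled explicitly (identical responses →
  non-selective; zero residual variance with group differences → p ≈ 0).
* **Tuning fits** use the bimodal Gaussian with angular differences
  wrapped to (−180°, 180°], multi-started over the 12 stimulus
  directions, ties broken toward smaller σ, and canonicalized so
  R_pref ≥ R_oppo with θ_pref in [0°, 360°). Fits are only meaningful
  downstream of the selectivity gate.
* **gOSI** takes the modulus of the 2θ-phasor mean (reported values are
  nonnegative scalars, though the defining ratio is complex), and
  negative mean responses are floored at zero first so the index stays
  in [0, 1].
* **Dominant orientation** folds preferred directions into 0–180°,
  histograms at 15° bins, and fits offset + wrapped Gaussian; if the
  Gaussian explains <30% of the flat model's residual sum of squares the
  histogram is declared to have no dominant peak.

`generate_session()` writes baseline × (1 + tuned transient) + Gaussian
noise, with exponential rise/decay kernels (0.1/1.5 s "calcium",
0.01/0.15 s "glutamate") normalized so the kernel's mean over the
grating epoch is 1 — making the evoked-response estimator unbiased for
the ground-truth amplitudes — plus multiplicative trial jitter. It
emulates trial-structured tuning and additive noise; it does *not*
emulate neuropil contamination, motion, bleaching, or spike-to-indicator
nonlinearity, so passing recovery tests demonstrate the estimators, not
robustness to those artifacts. Calibration facts the acceptance suite
computes on this generator: θ_pref recovery within ±10° in ≥95% of 500
noisy curves (10% noise, 20 trials), ANOVA false-positive rate 5 ± 1.5%
on 2000 null ROIs, and monotone loss of transient detection and gOSI as
SNR drops — the mechanism by which aberration correction changes
measured physiology.

## Problem sizes and numerical hygiene

Unit tests run at grid 128–256; the sensitivity scan and the headline
FWHMs use grid 512 (the package's convergence tests show FWHMs move <1%
when the grid doubles); the bead forward model renders 0.05-µm voxels on
a 1024 pupil grid. The closed-loop property uses 20 seeded aberrations
at grid 192. All randomness flows through explicit seeds; correction
patterns are bit-deterministic for identical inputs. Degenerate inputs
(empty annuli, under-sampled gratings, blank sensing tiles, non-positive
baselines, all-zero responses, flat histograms) error or flag rather
than silently producing numbers.
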