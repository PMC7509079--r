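---
title: "Measuring longitudinal spinal cord atrophy: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring longitudinal spinal cord atrophy: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Spinal cord atrophy — the slow loss of cord tissue — is one of the main
structural substrates of disability progression in multiple sclerosis, and a
candidate outcome measure for trials of neuroprotective drugs. Measuring a
1–2 %/year volume change in a structure roughly 8 mm across, from scans a
year apart, puts extreme demands on the measurement pipeline: the change at
the cord boundary is a small fraction of a voxel.

Two families of methods exist.

* **Segmentation-based (CSA / MUCCA).** Segment the cord at each timepoint
  independently, compute the mean cross-sectional area over a cord-level
  window, and subtract:
  `Δ% = 100 · (CSA_followup − CSA_baseline) / CSA_baseline`.
  Any independent segmentation error at either timepoint lands directly in
  the difference.
* **Registration-based (GBSI, the generalised boundary-shift integral).**
  Straighten the cord at both timepoints, register the two straightened
  volumes with a symmetric, inverse-consistent 9-degrees-of-freedom affine
  transform into the halfway space, and integrate the windowed intensity
  change over a probabilistic boundary-shift region. Because the comparison
  is made jointly on intensities, sub-voxel boundary shifts are captured by
  partial-volume changes, and independent segmentation errors only affect
  the measurement indirectly (through the integration region, not the
  value).

This package implements both branches end to end, together with the
supporting machinery a study needs: a noise-floor estimator for scan quality
control, an implausibility filter, trial sample-size calculators, clinical
progression definitions and covariate-adjusted cohort models — and a
synthetic phantom generator that provides ground truth for every stage.

## The GBSI pipeline, stage by stage

**Centerline and straightening.** The cord centerline is the per-slice
probability-weighted centroid of the mask, smoothed along the axis with a
low-order smoothing spline (8 effective degrees of freedom by default —
enough for anatomical curvature, too stiff for voxel noise). The volume is
resampled on planes perpendicular to the centerline using a
rotation-minimizing frame (no axial twist), trilinear interpolation,
in-plane spacing equal to the input spacing, and an axial step equal to the
mean centerline point spacing. Two numerical details matter:

* perpendicular planes near the volume faces tilt slightly past the
  first/last slice when the cord is curved; the axial sampling coordinate is
  clamped at the faces (edge replication along the axis only), because the
  cord in truth continues through the face and zero-filling would bite
  crescents out of the end slices;
* a curvature guard rejects centerlines whose curvature radius is smaller
  than the in-plane field of view, where perpendicular planes would
  self-intersect.

**Registration.** The transform family is translation (3) + rotation (3) +
shear (3), deliberately excluding scale: a scale parameter would absorb the
very atrophy signal being measured. The linear part is composed as
`Rz·Ry·Rx·Shear` with a unit-diagonal shear matrix, so its determinant is
exactly 1. The similarity metric is the mean squared intensity difference
computed **in both directions** (moving onto the fixed grid through `T`, and
fixed onto the moving grid through `T⁻¹`) and averaged, after each image is
divided by its median cord intensity; this makes the cost symmetric in the
two inputs, which is what gives inverse consistency under input swap. The
optimizer is BFGS from an identity start over a fixed three-level
multi-resolution schedule (4×, 2×, 1× block-mean downsampling), relative
tolerance 1e-6 — fully deterministic. Two robustness details: during
optimization, rotations and shears act about the volume centre (about the
world origin they would mimic translations at the object and condition the
problem badly; the result is converted back to the origin convention), and
a voxel that maps outside the other image is charged the squared difference
against that image's mean intensity — averaging over the valid overlap only
would reward degenerate transforms that shrink it. A run that exhausts its
iteration cap is accepted only when the residual is at interpolation-noise
level (below 1e-6 in normalized-intensity² units), i.e. numerically exact
alignment; otherwise it errors with the residual attached.

**Halfway space.** The halfway transform is the principal matrix square
root of the full 4×4 affine (Denman–Beavers iteration, verified by
composition to 1e-6). The baseline is sampled through `H⁻¹` and the
follow-up through `H`, onto a common grid, masks carried by the same warps.
Both members pass through exactly one identical interpolation step,
differing only in which half transform they receive — the construction that
avoids interpolation bias between timepoints.

**Boundary-shift region.** The region where the boundary may have moved is
estimated adaptively from both probabilistic masks:
`w = clamp(max(dilate(p_b), dilate(p_f)) − min(erode(p_b), erode(p_f)), 0, 1)`
with one-voxel 3×3×3 grey-value morphology. The shell width is a flag
(`width`), defaulting to one voxel; wider shells tolerate larger boundary
displacements but integrate more noise.

**Integration.** Intensities are normalized per-member by the median cord
intensity, and the clipping window is taken from the data: `low` = mean
normalized CSF-ring intensity, `high` = mean normalized cord intensity,
pooled over both timepoints. The volume change is

```
ΔV = voxvol / (high − low) · Σ_x w(x) · (clip(I_b(x)) − clip(I_f(x)))
```

with positive ΔV meaning volume loss (the cord is brighter than CSF on
T1-weighted images). The reported percent change is
`−100 · ΔV / V_baseline`, annualized with 365.25-day years using the actual
scan interval. The integration is restricted to an interior slice window
(default: 6 slices of margin at each end): the cut faces at the ends of the
acquired volume are not anatomy, and any axial misregistration there would
otherwise leak whole end-cap discs into the integral — on noisy phantoms
this single choice reduced the registration-induced error by roughly a
factor of five.

## The phantom: what it emulates, and what it does not

The phantom is a curved tube (sinusoidal centerline, amplitude 2.5 mm,
period 50 mm by default) of cord-bright tissue, radius 4.5 mm, inside a CSF
ring of outer radius 7.5 mm, on a 48×48×64 grid of 1 mm isotropic voxels —
dimensions chosen to mimic an upper-cervical cord acquisition (cross-section
≈ 64 mm², realistic curvature, C1–C5-like coverage). Default intensities
are cord 500, CSF 100, background 20 (arbitrary units), i.e. the
suppressed-CSF contrast of a T1-weighted scan.

Atrophy is applied as uniform radial shrinkage: the follow-up radius is
`r·sqrt(1−f)`, so follow-up volume is exactly `(1−f)` times baseline for the
unchanged centerline, and the vacated shell is filled by CSF. Partial volume
at the cord and ring surfaces is modelled by 3×-per-axis supersampling of
boundary voxels; each subvoxel contributes a planar-cut occupancy ramp of
its own width rather than a hard 0/1 count, because the shell between two
nearby radii (0.02–0.1 mm) is far thinner than the subvoxel lattice
(0.33 mm) and hard counts alias badly against it. Noise is Rician —
the magnitude of signal plus complex Gaussian noise, drawn independently per
timepoint — with the default study condition `σ = 20`, one twentieth of the
cord/CSF contrast. The default interval is 365.25 days, so annualized rates
equal raw percent changes and ground truth is simply `−100·f`.

For cohort simulations, working masks are re-derived from the *noisy*
images by intensity thresholding, binarized at probability 0.5
(`segment_cord()`). This is the step that emulates the automated
segmentation of a real pipeline: CNN segmenters emit (near-)binary masks,
and the boundary quantization driven by image noise is precisely what makes
segmentation-based CSA noisier than the intensity-integrating GBSI on the
same inputs. Without it — with the phantom's analytic partial-volume masks —
CSA would be nearly noise-free and the variability comparison meaningless.

The phantom deliberately does **not** model lesions, scanner drift between
timepoints, gradient-nonlinearity distortion, coil-profile inhomogeneity or
vendor differences. Passing tests therefore demonstrate correctness of the
measurement machinery under controlled noise, not robustness to every
real-world artefact; the real-data failure modes (poor contrast, artefacts,
segmentation failures) are exactly what the noise-floor QC and the
implausibility filter exist to catch.

## Noise floor and quality control

T1-weighted CSF is nearly signal-free, so the magnitude signal in a ring of
CSF around the cord is Rayleigh distributed with
`SD = σ·sqrt(2 − π/2)`, where σ is the Gaussian channel SD. The ring is the
cord mask dilated twice in-plane with a 3×3 square element, minus the mask;
values more than 2 population SDs above the ring mean are discarded once
(one-sided — the trim exists to remove bright nerve roots and similar
contamination), and the corrected noise floor is
`σ = SD(retained) / sqrt(2 − π/2)`. Scans are classified against the median
σ of their cord level.

A calibration caveat that users should know: on *clean* Rayleigh data the
one-sided trim removes about 3.7% of the legitimate upper tail, and because
an SD is tail-sensitive this attenuates the corrected σ by a factor of
about 0.88 (measured by Monte-Carlo at 10⁶ voxels; the package's tests pin
this value). On contamination-free data `reject = FALSE` gives an unbiased
estimate; with the trim the estimator should be read as a *relative*
quality index — which is how it is used (median split) — rather than an
absolute σ.

The implausibility rule excludes a measurement only when **both** CSA and
GBSI exceed ±5 %/year at the same cord level — a conjunctive, two-sided
rule (the cut-off corresponding to twice the healthy-control rate SD);
filtering is idempotent and missing values defer the decision rather than
excluding.

## Trial design and cohort statistics

Sample size per arm for a 1:1 two-arm trial on an atrophy rate uses the
standard normal-approximation formula

```
n = ceil( 2 · (z_{1−α/2} + z_{power})² · σ² / Δ² ),   Δ = effect · |mean|
```

with two-sided α = 0.05 and power 0.80 as defaults. Two conventions were
genuinely open and are fixed here: α is two-sided, and rounding is ceiling —
this pair reproduces the published MUCCA-based entries (518 per arm at a
60% effect, 230 at 90%, from −0.9 ± 3.1 %/year). The published 30% entry
(2073) is *not* recoverable from the rounded summaries (they give 2070);
it evidently stems from unrounded source data, and the package documents
rather than chases it. A Monte-Carlo verifier (`verify_power()`) simulates
two-arm z-tests at the computed n and reproduces the nominal power and
type-I error; variability is additionally summarized by the signed
coefficient of variation (sample SD / mean) and the raw (unscaled) median
absolute deviation.

Progression rules are implemented exactly as defined: EDSS progression is
≥ 1.0 point from baseline when baseline ≤ 5.5 and ≥ 0.5 point when baseline
> 5.5; timed-walk, pegboard, symbol-digit and walking-scale progression is
a ≥ 20% increase from baseline (boundary inclusive). Treatment contrasts
use OLS with the arm indicator plus the confounders age, sex, height,
country (as categorical indicators — the natural encoding for a 10-country
trial) and baseline CSA; confidence intervals use the t distribution with
residual degrees of freedom. The clinical-correlate screen is backward
*elimination* with a stay threshold of p = 0.20 (the conventional reading
of a backward procedure quoted with an entry-style threshold); the
confounders are exempt from elimination, since they are listed as
confounders rather than candidates.

## Problem sizes used by the validation suite

The test suite and the acceptance script regenerate everything from code:
default-resolution phantoms (48×48×64) for ground-truth recovery (three
atrophy levels noiseless, ten noise seeds per level), a 50-phantom noisy
cohort for the CSA/GBSI variability comparison, ≥ 10⁴-voxel pure-noise
rings for noise-floor calibration, and 10⁴ Monte-Carlo replicates for the
power checks. These sizes were chosen so that Monte-Carlo error is well
inside each assertion's tolerance.

## Known limitations

* The registration is affine-only (by design — the cord is straightened
  first); no deformable refinement or distortion correction is attempted.
* The intensity window is estimated from the data (mean ring / mean cord
  intensity); on pathologically low-contrast scans `normalize_pair()`
  refuses to proceed rather than guessing.
* The noise-floor estimator's trim attenuation on clean Rayleigh data
  (≈ 0.88, above) is inherent to the stated procedure.
* Vertebral-level identification is out of scope: level ranges are slice
  windows supplied by the caller (phantom levels are defined by
  construction).
* The phantom's segmentation emulation is an intensity threshold; it
  reproduces the noise-propagation mechanism of automated segmenters, not
  their anatomy-driven failure modes.
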