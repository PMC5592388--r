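---
title: "Removing arterial contamination from SWI venography: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Removing arterial contamination from SWI venography: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement and why it needs correcting

Susceptibility-weighted imaging (SWI) is a velocity-compensated 3D
gradient-echo sequence in which paramagnetic deoxyhemoglobin makes venous
blood hypointense. Venous conspicuity is quantified as the normalized
visible venous volume (NVVV): the volume of hypointense vessel voxels
above the M1 segment of the middle cerebral artery divided by the
intracranial volume above the same plane. The vessel voxels are found by
a two-dimensional multiscale Frangi vesselness filter applied to a 16 mm
sliding minimum-intensity projection (mIP) of the SWI, keeping voxels
whose vessel "probability" strictly exceeds 0.60.

Linear flow compensation nulls phase only for constant-velocity spins.
In high-flow, tortuous arteries — the typical cerebrovascular picture in
sickle cell disease — higher-order flow survives, and large arteries can
appear as dark as veins. A venous-volume measurement that cannot tell
them apart overestimates NVVV. The correction implemented here uses the
arterial information already acquired in the same session: a
time-of-flight (TOF) MR angiogram, in which arteries are bright.

## The correction pipeline

1. **Rigid coregistration.** The TOF volume is aligned to the SWI by
   maximizing normalized mutual information (NMI), the ratio
   `(H(A)+H(B))/H(A,B)` over a 64-bin joint intensity histogram with
   intensities clipped at the 0.5–99.5 percentile range (a few very hot
   arterial voxels otherwise dominate the binning). Six rigid parameters
   suffice for a skull-fixed brain scanned in one session. Because
   hard-binned NMI is piecewise-flat at sub-bin scales, a derivative-free
   Nelder–Mead simplex is used, coarse-to-fine over a 3-level Gaussian
   pyramid, initialized at the pose implied by the image headers. Two
   simplex passes are run per level — a wide one (initial steps ≈0.6° /
   0.8 mm) to step over the binning plateau, then a narrow one for
   sub-voxel refinement — and the optimizer never returns a point worse
   than its start. A user-supplied transform (4×4 world-mm text matrix)
   bypasses estimation, supporting externally registered data. Every run
   reports NMI before and after; a transform that lowers NMI fails QC and
   aborts the pipeline unless explicitly overridden.

2. **Arterial mask.** Bright-polarity Frangi vesselness of the MRA,
   thresholded strictly at 0.75, dilated in-plane with a Euclidean disk
   of 2 voxels *on the native MRA grid* — where "2 voxels" has its
   physical meaning (0.82 mm at a 210/512 mm in-plane spacing) — then
   resampled to the SWI grid with nearest-neighbour interpolation and
   re-binarized at 0.5. The dilation absorbs partial-volume rims and
   residual misregistration; a disk (dx²+dy²≤r²) is the declared
   structuring element, isotropic in-plane. Dilation never crosses
   slices.

3. **Masked projection.** Arterial voxels are excluded from each mIP
   window's minimum in the original SWI space, *before* projection:
   masking the projected image instead would erase veins lying behind
   arteries anywhere in the 16 mm slab. A window whose every voxel is
   excluded (an artery running parallel to the slab) is set to a
   hyperintense fill value so it cannot re-read as a dark vessel.

4. **Quantification.** Dark-polarity segmentation of the corrected and
   uncorrected mIP stacks, NVVV above the M1 plane for both (uNVVV,
   cNVVV), and the arterial contamination fraction
   `(uNVVV − cNVVV)/uNVVV`. With the published cohort means uNVVV =
   0.012 and cNVVV = 0.008 this fraction is one third — the package's
   worked example.

## The vesselness filter

For each axial slice and scale σ, the image is convolved with sampled
Gaussian-derivative kernels (support ±max(3, ⌈4σ⌉) pixels, reflective
boundary) to obtain the Hessian, scale-normalized by σ² so scales compete
fairly (γ = 2). The kernels' discrete moments are corrected exactly —
zero DC response for the second-derivative kernel, exact first/second
moments — so a constant image has an identically zero Hessian and a
quadratic image an exact one; without the correction, the ~10⁻⁴ residual
DC of a sampled kernel leaks image brightness into the Hessian.

With eigenvalues `|λ1| ≤ |λ2|`, vesselness is
`exp(−R_B²/2β²)(1 − exp(−S²/2c²))` where `R_B = λ1/λ2` penalizes
blob-like structure and `S = √(λ1²+λ2²)` suppresses flat noise; the sign
of λ2 implements the polarity rule (dark tubes λ2 > 0, bright λ2 < 0;
λ2 = 0 scores zero, avoiding the undefined ratio). The per-pixel maximum
over scales is the output, read as a probability in [0, 1].

Parameter meanings and defaults:

| parameter | default | unit | role |
|---|---|---|---|
| β | 0.5 | — | blobness sensitivity |
| c | 20 | intensity | structureness scale; meaningful on a 0–255-like range |
| scales | 1–3 | voxels | venule-to-artery radii at clinical resolution |
| vein threshold | 0.60 | probability | strict, per the "> 60%" rule |
| artery threshold | 0.75 | probability | strict, per the "> 75%" rule |
| dilation | 2 | MRA voxels | in-plane disk radius |
| slab | 16 | mm | mIP thickness; 8 slices at 2.0 mm |

`c` is *not* dimensionless: images on other intensity scales need a
rescaled `c` or a rescaled image. The phantom generator emits 0–255-like
intensities for exactly this reason. Whether intensities should be
normalized before filtering is an open acquisition-dependent question;
this package declares the convention rather than guessing another one.

## Numerical conventions

* World coordinates follow the NIfTI affine (0-based voxel indices); all
  geometry is computed in world millimetres, so the SWI and finer MRA
  grids interoperate without index arithmetic.
* Resampling fills out-of-field voxels with 0 (a dark MRA background);
  linear interpolation for intensities, nearest-neighbour for masks
  (value sets are preserved).
* The sliding window is anchored at its leading (inferior) slice and
  truncated at the superior volume edge, so the mIP stack keeps the
  slice count of its input; window length is `round(thickness/spacing)`.
* The hyperintense fill is the 99th percentile of in-brain SWI
  intensities — robust to single bright outliers, bright enough never to
  be re-detected as a vessel — floored at the raw window minimum so that
  exclusion can never darken a voxel below its unmasked projection.
* Both NVVV values are counted on the mIP stack (a vein contributes to
  every overlapping slab that sees it). NVVV is an operational ratio;
  numerator conventions cancel in the contamination fraction, which is
  the quantity of scientific interest. The stack count runs well above
  the volumetric vein fraction (replication across ~8 slabs, offset by
  the strict threshold keeping only dark cores), which is why phantom
  validation targets the contamination fraction, not absolute NVVV.
* Vesselness is computed on the mIP with non-brain voxels set to the
  in-brain 99th percentile, and the window minimum is taken over
  in-brain voxels only; otherwise the dark surround leaks into windows
  crossing the superiorly tapering brain edge and reads as a ring of
  spurious veins.
* The M1 plane is a user-supplied axial slice index ("above" = higher
  slice index); no automatic anatomical detection is attempted.

## The phantom generator

Each phantom is a pair of volumes over a 105 × 105 × 56 mm field of
view: an SWI grid of 64 × 64 × 28 voxels at 1.64 × 1.64 × 2.0 mm and an
MRA grid of 112 × 112 × 40 voxels at 0.82 × 0.82 × 0.8 mm. Slice
thicknesses match a clinical protocol (2.0 mm SWI, 0.8 mm MRA); the
in-plane spacings are twice clinical so the full validation suite runs
in minutes — the package's choice of problem size, stated here once.

The scene is built in world coordinates: a brain ellipsoid with unequal
in-plane semiaxes (45 × 38 × 24 mm — a rotationally symmetric brain
would leave in-plane rotation unidentifiable and make registration tests
vacuous), two ventricle-like ellipsoids (bright on SWI, dark on TOF,
interior landmarks that carry mutual information), six parasagittal
cortical-style veins (straight tubes, 1.1–1.3 mm radius, running
anteroposteriorly), two basal arteries below the M1 plane (TOF-bright
only), and zero to four tortuous contaminating arteries — helices of
1.4–1.7 mm tube radius winding about anteroposterior axes in the lateral
bands, dark on SWI and bright on TOF. Vein and contaminating-artery
territories are spatially disjoint, as in real anatomy (Sylvian arteries
lateral to the parasagittal venous drainage); when tubes were allowed to
crisscross, vessel junctions in the projection suppressed the Frangi
response enough to bias the measured contamination downward. The
contaminating arteries also keep a clearance above the M1 plane larger
than the slab thickness, because the leading-anchored projection smears
structures inferiorly by up to 7 slices and an artery hugging the cut
loses most of its stack replicas below it.

Tubes are rasterized at 2× supersampling and box-downsampled, giving
partial-volume soft edges; the solid is a capsule (centerline distance
test). The TOF channel is rendered *through* the specified rigid
misalignment, so registration recovery can be validated against a known
pose. Gaussian noise (SD 4 on the 0–255 scale) is added under a stored
seed; truth masks are noise-free voxel-centre rasterizations. Rician
magnitude statistics are deliberately not modelled; at the phantom's SNR
the Gaussian approximation is benign and declared.

Four presets grade the contamination like a 0–III visual score:
`score0` (none, true fraction 0), `score1` (one artery, 0.225), `score2`
(two, 0.363 — the "about one third" regime), `score3` (four, 0.530).

## What the phantom validation does and does not show

Passing tests demonstrate: the filter mathematics agree with brute-force
oracles to 10⁻¹⁰; masked projection is exactly the minimum over unmasked
window voxels; registration recovers random rigid poses (≤ 5°, ≤ 6 mm)
to sub-voxel median accuracy; and the full pipeline recovers known
arterial contamination fractions to ±0.15 absolute while leaving venous
signal intact (uNVVV and cNVVV within 5% when no contamination exists).

They do not demonstrate performance on clinical data: phantoms have no
susceptibility physics, no phase-mask processing, no motion, no skull or
scalp, piecewise-constant tissue, and Gaussian noise. The brain-mask
fallback (Otsu threshold, largest 6-connected component, 3 mm
morphological closing, hole filling) is adequate for these phantoms and
is *not* a substitute for a proper skull-stripping tool on real images —
supply an external brain mask there. Arterial correction quality on real
data is further bounded by MRA coverage and flow-related enhancement,
neither of which the phantom stresses.

## Known limitations

* 2D slice-wise vesselness underdetects steeply through-plane vessel
  segments on thick-slice data; the in-plane dilation of the arterial
  mask partly compensates.
* The strict 0.60 threshold keeps only the dark core of each projected
  vein, so absolute NVVV is convention-dependent (see above); comparisons
  should always use a fixed convention, as the contamination fraction
  does.
* The registration is rigid by design; it cannot express gradient
  distortion differences between the SWI and TOF acquisitions.
* A dilation radius large enough to swallow veins running parallel and
  close to arteries would bias cNVVV downward; the phantom suite bounds
  this (arterial mask overlaps < 2% of vein volume at ≥ 2× dilation
  separation) but close vein-artery pairs in real anatomy remain the
  user's judgement call.
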