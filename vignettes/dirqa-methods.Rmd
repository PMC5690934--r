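---
title: "Benchmarking deformable registration with ground-truth phantoms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking deformable registration with ground-truth phantoms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dirqa)
```

## The problem

Deformable image registration (DIR) underpins adaptive radiotherapy: dose
computed on later anatomy is mapped back onto the planning CT through a
deformation vector field (DVF), and clinical decisions rest on that mapping.
Commercial DIR systems are black boxes, and on real patient pairs there is no
ground truth to score them against. dirqa provides the benchmarking loop a
physicist needs to commission such a system: virtual head-and-neck phantoms
whose deformation is known exactly, controlled ways to produce imperfect test
DVFs, and the metrics that connect spatial registration error to its
dosimetric consequence.

The central quantity is the voxel-wise target registration error,
$\mathrm{TRE}(x) = \lVert u_\text{test}(x) - u_\text{gt}(x) \rVert$, the
distance between where a test DVF and the ground-truth DVF send the same
voxel. Per organ we summarize its mean ($\mathrm{TRE}_\mu$), population SD,
maximum, and the fraction of voxels within 2 mm (the TG-132 goal is 95%
within 2 mm). On the dose side we pull the end-of-treatment (EOT) dose back
to the start-of-treatment (SOT) anatomy through both fields and score the
difference in mean dose, maximum dose, and the mean point-by-point
dose-volume-histogram difference ($\Delta\mathrm{DVH}_\text{mean}$, in Gy).
The synthesis stage correlates $\mathrm{TRE}$ metrics with dose-error
metrics across a suite of phantoms and registration sources.

## Conventions

All grids are regular and axis-aligned with 0-based voxel indices and a
voxel-center world mapping `world = origin + index * spacing`, lengths in mm.
A displacement field lives on the SOT (target) grid and maps target points
into EOT space, $\varphi(x) = x + u(x)$; dose and image warping are
pull-backs, `out(x) = moving(x + u(x))` with trilinear interpolation. A field
imported with the opposite convention declared in its sidecar is inverted at
load time.

Two out-of-hull policies coexist deliberately. Scalar volumes return a
declared fill value (0 for dose, the image minimum for CT-like images) and
flag the points: extrapolated HU or dose is meaningless. Displacement
components, however, are sampled with edge extension (clamped trilinear).
Field algebra needs a total function: with a zero fill, the fixed-point
inverse of even a constant translation fails to converge at the boundary,
and the demons update sees spurious intensity jumps at the volume faces.

The trilinear kernel uses the symmetric two-product form
$(1-f)\,v_0 + f\,v_1$ per axis, which is exact at both endpoints, so
sampling at any voxel center — including the clamped far faces — returns the
stored value bit-identically and a zero-field warp is the identity.

## Phantom synthesis

`build_anatomy()` constructs a CT-like head-and-neck volume from analytic
shapes: an ellipsoidal head fused with a cylindrical neck (the external
contour), a cranial bone shell, a vertebral column surrounding the spinal
cord, the brainstem continuing above it, a mandibular arc, and two parotid
ellipsoids. Organ masks are exact level sets of these shapes, clipped to the
external contour the way drawn contours are; they are pairwise disjoint by
construction. Tissue HU values get a low-frequency texture field (SD 25 HU,
12 mm correlation length) so soft tissue is not featureless for
intensity-driven registration, then a 0.8-voxel Gaussian blur emulating
partial-volume averaging, then white Gaussian noise (SD 5 HU). The blur
matters beyond realism: it band-limits the image so that the double
interpolation in the EOT round trip stays small at bone edges.

`build_ground_truth_mapping()` composes analytic deformation components in a
fixed order (head applied innermost): rigid head rotation and translation,
spine flexion, mandible rotation, parotid shrinkage, weight loss, and a
thin-plate-spline residual. Defaults describe a typical end-of-course
change: 2° head rotation with a (2, 1, 0) mm translation, 0.2°/cm neck
flexion saturating at 8 cm, 3° mandible rotation, 25% parotid volume loss
with a 25 mm Gaussian envelope, 4 mm peak inward surface regression with a
25 mm depth falloff, and a 2 mm TPS residual expressing nodal shrinkage.
Localized soft-tissue changes that do not merit dedicated analytic
components — tumor/node shrinkage, hyoid shift, shoulder drift — are
available as TPS control-point presets (`tps_preset()`), which is adequate
for an evaluation tool whose purpose is known deformation, not biomechanical
fidelity.

Three blending devices keep the composition a small-deformation
diffeomorphism. Rigid-like components are multiplied by a C¹ body-support
window (a smoothed external mask) so the DVF vanishes in air away from the
patient, where a deformation has no meaning and where large displacements
near the grid boundary would make the numerical inverse ill-conditioned.
The weight-loss field is $\text{peak} \cdot 4b(1-b)\,\nabla b / \max\lVert
\nabla b\rVert$ for the smoothed body indicator $b$ — scaling by the
gradient magnitude rather than normalizing it avoids the direction
discontinuity on the medial axis where $\nabla b \to 0$. Finally the
composite is tapered to zero within 9 mm of the grid boundary. Positivity of
the Jacobian determinant is verified per component (failures name the
component) and for the composite.

Parotid shrinkage deserves a note: the contraction strength of the radial
Gaussian field is calibrated by bisection so that the mean Jacobian
determinant over the parotid mask equals $1 - f$ for requested volume loss
$f$; since $\int_\text{mask} \det(I + \nabla u)\,dx$ is the volume of the
forward-warped mask, the warped parotid loses the requested fraction by
construction rather than by an approximate closed form.

The EOT image is $\mathrm{EOT}(y) = \mathrm{SOT}(y + v(y))$ with $v$ the
fixed-point inverse of the ground-truth field (tolerance 0.01 mm, at most 50
iterations; the maximum update per sweep equals the composition residual, so
convergence certifies $\lVert\varphi(\varphi^{-1}(y)) - y\rVert <
\text{tol}$), plus independent Gaussian noise. Build fidelity — the RMS
error of `warp_volume(eot, gt_field)` against the SOT image inside the
external mask, normalized by the image intensity range — is checked against
a declared tolerance (2% on the 3 mm study grid; coarser grids declare
looser bounds because interpolation error at tissue boundaries grows with
voxel size).

Each phantom in a suite emulates a different patient: organ geometry is
jittered within anatomically safe ranges and every deformation-component
magnitude is scaled by an independent uniform factor (±30% by default),
mirroring the patient-to-patient spread of anatomical change over a
treatment course. The whole phantom is a pure function of (config, seed).

## The dose model

`synthesize_dose()` places an ellipsoidal target and assigns
$D(x) = D_\text{rx}\, s(d(x))$, where $d$ is the signed ellipsoidal distance
to the target surface and $s$ is 1 inside the target and, outside, a steep
Gaussian penumbra (σ = 5 mm) plus a broad low-dose bath (relative weight
0.15, σ = 120 mm) emulating the scatter and entrance dose of a rotational
IMRT delivery. The prescription is a single 2 Gy fraction. The bath is not
cosmetic: without it, organs beyond a few penumbra widths receive
numerically zero dose, percent dose errors become undefined, and — because
even a tiny residual gradient makes dose error exactly proportional to a
coherent registration error — distant organs would show the same perfect
TRE-dose correlation as abutting ones.

The gradient-placement knob: when no explicit target center is given, the
target is shifted along the line away from the chosen organ-at-risk centroid
until the 50% isodose sits `gradient_margin` mm from the nearest OAR voxel
(default 2 mm from the brainstem, computed against the deformed OAR since
the plan belongs to the EOT anatomy). This is the distance-to-gradient
mechanism that makes identical registration errors dosimetrically harmless
for one organ and consequential for another.

## Test DVFs

`demons_register()` is a classic multi-resolution intensity demons: per
voxel the update is the passive-force step
$(f - m\circ\varphi)\,\nabla f / (\lVert\nabla f\rVert^2 + (f -
m\circ\varphi)^2)$, capped at 0.8 voxel, with the field Gaussian-smoothed
(σ = 4 mm) after every iteration, run coarse-to-fine over 3 levels (60, 40,
20 iterations) with trilinear field upsampling. No initial rigid
registration is applied, and a global intensity offset of both images leaves
the result unchanged. The sign of the update is the one that contracts
toward registration under pull-back warping; the opposite sign amplifies
displacement along image gradients and visibly diverges on
self-registration.

`inject_error()` perturbs the ground truth with a known error, giving every
benchmark metric a planted truth: a constant `bias` (TRE equals the
magnitude everywhere, exactly), `smooth_noise` (per-component Gaussian
random fields at a chosen correlation length, rescaled so the mean error
norm over a mask matches the magnitude exactly up to mask sampling), and
`local_blob` (a compactly supported bump $(1 - (r/R)^2)^2$, emulating an
isolated gross misregistration confined to one structure, with exactly zero
error outside its support).

## Metric choices the data could not settle

* $\Delta\mathrm{DVH}_\text{mean}$ is computed on the volume axis: both
  cumulative DVHs are inverted to dose-at-volume $D(v)$ by linear
  interpolation and averaged as $\frac{1}{99}\sum_{v=1\%}^{99\%}
  \lvert D_\text{test}(v) - D_\text{gt}(v)\rvert$ — the absolute version is
  reported (signed retained alongside) because the quantity is used as an
  error magnitude; its unit (Gy) forces the volume-axis sampling.
* Percent mean-dose error is normalized by the ground-truth mean dose of the
  ROI (undefined and reported missing when that mean is zero), not by the
  prescription.
* ROI statistics use the population SD (the ROI is the whole population of
  its voxels). The failure rule pools all $\mathrm{TRE}_\mu$ entries for an
  ROI across phantoms and sources and flags entries at or above the pooled
  mean plus two population SDs; the boundary is inclusive so that an entry
  sitting exactly two SDs out is treated as the failure it describes.
* Correlation-strength wording uses the 0.2/0.4/0.6/0.8 bands on $\lvert r
  \rvert$ (very weak / weak / moderate / strong / very strong).
* Source comparisons use a paired two-sided t-test on per-phantom
  $\mathrm{TRE}_\mu$ with $df = n - 1$ pairs; a zero-variance difference
  vector is reported as degenerate rather than forced through the test.
* TRE histograms default to 0.5 mm bins, half-open, last bin extended to the
  maximum.

## Suite design for the correlation analysis

A subtle point governs the default registration-source set. Pearson
correlation is scale-free: if every test DVF is a coherent bias of graded
magnitude, each organ's dose error is essentially proportional to the bias —
with a large constant for an organ abutting the penumbra and a tiny one for
a protected organ — and $r \approx 1$ for *both*. The qualitative contrast
between a gradient-adjacent organ (strong TRE-dose correlation) and a
margin-protected one (weak correlation) only emerges when the error
*structure* varies across sources, as it does across real registration
algorithms. `default_sources()` therefore mixes graded gradient-aligned
biases (1–6 mm), two smooth-noise sources (1.5 and 3 mm at 30 mm correlation
length), the demons output, and the parotid blob. Under these study
conditions the brainstem (50% isodose 2 mm away) shows a strong-to-very
strong $r(\mathrm{TRE}_\mu, \Delta\mathrm{DVH}_\text{mean})$ while the
distant cord, sitting in the flat bath, falls to weak-to-moderate — the
ordering the acceptance suite asserts; the exact coefficients are computed,
not assumed, by `scripts/acceptance.R` and the test suite.

## What the generator does and does not emulate

The phantoms reproduce the *structure* of a DIR benchmark: paired volumes
linked by a known invertible deformation of clinically plausible magnitude,
organ contours, and a dose distribution with controllable gradient
placement. They are not anatomically or dosimetrically faithful patients:
shapes are analytic, deformation components are smooth and globally
invertible (no sliding interfaces, no appearing or vanishing air cavities,
no biomechanical tissue model), the dose is a geometric profile rather than
a transport calculation, and image artifacts beyond Gaussian noise are
absent. Consequently, a registration algorithm's score on these phantoms
measures its behavior under smooth, moderate deformation with honest
intensity correspondence — passing here is necessary, not sufficient, for
clinical performance, which is precisely the role of a commissioning
benchmark.

## Problem sizes and numerical tolerances

The study grid is 64³ voxels at 3 mm (192 mm extent); module tests exercise
the same geometry on a 32³/6 mm grid, where a phantom builds in about two
seconds, and kernel oracles run on ≤16³ fixtures. Field inversion uses
tolerance 0.01 mm with 50 iterations; TPS systems are solved densely (the
interpolation condition is met to ~10⁻⁷ mm); the parotid calibration
bisection stops at 10⁻⁵; demons runs the 3-level schedule above. The
acceptance script regenerates everything from a single seed: one study-grid
phantom for fidelity, inversion, error-recovery and demons quantities, a
linear-dose slab for the gradient-interplay prediction, and a 3-phantom ×
9-source suite for the correlation table.

## Known limitations

Imported vendor DVFs must be NIfTI with a sidecar declaring the direction
convention; DICOM Deformable Spatial Registration objects need an external
conversion step (a future adapter). Grids are axis-aligned with no direction
cosines. Resampling of imported fields onto the ground-truth grid is
trilinear per component, a choice the comparison protocol leaves open. Dose
warping is a pure pull-back with no energy or mass rescaling, and dose is a
single fraction — accumulation across fractions is out of scope.
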