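---
title: "Correlative micro-CT / histology registration for bone ingrowth in porous implants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlative micro-CT / histology registration for bone ingrowth in porous implants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Histomorphometry of bone growing into a porous metal implant faces a
sampling problem and a deformation problem.  A stained ground section is a
single 50--80 µm slab out of a ~2 mm implant, so it sees a few percent of
the tissue, preferentially near the implant edge; and the wet-lab
processing (fixation, dehydration, resin embedding, grinding) shrinks and
tears the soft and bony tissue by amounts that are themselves of scientific
interest.  Micro-CT sees the whole volume non-destructively but at lower
resolution and, around titanium, through metal artefacts.

`scafreg` implements the correlative strategy that reconciles the two
modalities: the titanium lattice itself is rigid through histology
processing, so the scaffold segmented from the 2D section can be rigidly
registered into the scaffold segmented from the 3D scan, independently of
the deformed tissue.  Once the section's pose inside the volume is known,
the "corresponding 2D micro-CT" plane can be extracted and the two
modalities compared pixel for pixel: bone ingrowth (BI), bone--implant
contact (BC), and the tissue shrinkage itself become measurable.

Because no public specimen data exist for this workflow, the package ships
a fully ground-truthed synthetic world (the `phantom` functions): every
downstream claim is tested against phantoms whose true BI, BC, pose and
shrinkage are known by construction.

## The model, stage by stage

### Scaffold phantom

`make_scaffold()` voxelises a cylinder-clipped lattice of three orthogonal
families of cylindrical struts (defaults: cylinder Ø 3 mm × h 1.8 mm,
strut Ø 180 µm, pitch 400 µm, 9 µm voxels).  The pitch is not a printed
design value; 400 µm is fixed because the inclusion--exclusion volume of
the unit cell — three cylinders $\pi r^2 a$, minus three Steinmetz
intersections $16r^3/3$, plus the triple intersection $8(2-\sqrt2)r^3$ —
then reproduces the implant's stated 65 % porosity, making the porosity an
internal consistency check (`analytic_scaffold_porosity()`).

Two deliberate departures from the ideal CAD lattice matter:

* **Node-sharing phases.** The three strut families share per-axis lattice
  phases so struts meet at nodes (as built, and as the analytic formula
  assumes), and the whole lattice is phase-offset from the cylinder axis
  so the clipped cylinder has no exact 90° rotation symmetry.
* **As-built roughness** (`roughness_um`, default 15 µm): each strut gets
  its own axis jitter and its own smooth axial radius profile, centred so
  the expected cross-section (hence porosity) is unchanged.  This is not
  cosmetic: an ideal node lattice is exactly symmetric under mirrors and
  whole-pitch translations, so a single section could be registered to it
  at several poses with near-equal similarity.  Selective-laser-melted
  struts are rough at the tens-of-microns scale, and that roughness is what
  makes the physical registration problem well posed; the phantom models
  it for the same reason.  The roughness uses a fixed internal seed — the
  as-built implant is one reproducible object, not a random variable.

### Implanted tibia, micro-CT and histology simulators

`make_tibia_phantom()` surrounds the scaffold with marrow and a cortical
annulus (the inner radius leaves a soft gap wide enough that a ~0.92
in-plane tissue shrink cannot drag the cortex under the implant rim), and
fills a controllable fraction of the pore space with new bone: a smooth
random field plus a radial gradient (`edge_bias`) emulating preferential
peripheral ingrowth.  The achieved BI/BC are counted exactly during
generation and are, by construction, identical to what `bone_ingrowth()` /
`bone_contact()` recompute from the stored masks — an identity the test
suite asserts.

`simulate_ct()` maps classes to intensities, blurs with a Gaussian PSF,
adds thin in-plane streak patterns windowed by the blurred titanium
neighbourhood (metal artefacts), and Gaussian noise; it deliberately stops
short of projection-space simulation (filtered back-projection and ring
artefacts are out of scope).

`simulate_histology()` extracts the label slab at a pose (nearest-neighbour
labels; titanium is opaque, so the titanium mask is the union over the slab
planes), then deforms the *tissue only*: anisotropic in-plane shrink about
the section centre, a separation gap opened where bone meets titanium, and
an optional smooth elastic warp — in that order.  The titanium label is
pointwise invariant under the deformation; that is the fiducial assumption
the whole method rests on, true here by construction.  Classes are coloured
with stain colours (titanium dark, bone pink, marrow purple, background
bright) plus multiplicative noise.

### Filters

* `normalize_histogram()`: monotone quantile matching through binned CDFs;
  rank order is preserved exactly, values to within a bin width (sparse
  histogram tails collapse to bin resolution).
* `anisotropic_diffusion()`: explicit Perona--Malik scheme, conductance
  $g = \exp(-(|\nabla I|/\kappa)^2)$, Neumann boundaries.  Defaults
  (10 iterations, $\kappa$ = 10 % of range, step 0.125 in 2D / 1/16 in 3D)
  are package choices; the step must respect the stability bound (0.25 in
  2D, 1/6 in 3D) and the scheme then conserves the mean exactly and obeys
  the maximum principle.
* `global_threshold()`: the calibrated `peak_average` method finds the
  highest-intensity histogram mode (titanium) per calibration image,
  averages across images, and cuts midway to the next-lower mode.  A
  threshold *at* the peak would halve the titanium; the midpoint honours
  the calibration intent and is testable.  Mode detection uses topographic
  prominence with a Poisson-noise floor so histogram noise never counts as
  a mode.
* `metal_artifact_correction()`: intensities within `band_um` of titanium
  are iteratively replaced by the median of their non-titanium
  neighbourhood (band included), stopping when the bone classification of
  the band stabilises.  An earlier variant that excluded the band from the
  sources — inpainting purely from outside — propagated streak-corrupted
  exterior values inward and demonstrably *worsened* the bone mask; the
  in-place median is what makes bone near titanium thresholdable, which is
  all the downstream quantification needs.

### Registration

The similarity metric is the correlation coefficient
$C = \sum (T_i - T_m)(R_i - R_m) / \sqrt{\sum (T_i - T_m)^2}\sqrt{\sum (R_i - R_m)^2}$
computed between binary titanium masks cast to reals; $C = 1$ is a perfect
match.  Registration never looks at bone or soft tissue.

`coarse_search()` is staged to stay tractable: (1) plane offsets ×
in-plane rotations (5° steps) are scanned flat and downsampled in compiled
code; (2) for the best few in-plane angles the offsets are re-scanned
*jointly* with the ±10° tilt grid — important because a tilt of θ moves
the best-matching flat offset by up to $\tan\theta$ times the field
half-width (~30 voxels at 10°), so a local search around the flat peak
fails; (3) survivors are re-ranked at full resolution with the full slab.
Ties break deterministically by offset then angles, so grid order never
matters.

`refine_rigid()` is a Nelder--Mead simplex over an in-plane (3 DOF) or
full rigid (6 DOF) correction composed with the initial pose, following
the section-thickness rule: a single-voxel slab constrains only an
in-plane transform; above 5 voxels all 6 DOF are stable; between, the
conservative 3 DOF default applies (configurable).  Three numerical
choices matter:

* mask slabs combine planes by **maximum** (union), matching how an opaque
  phase projects through a ground section; mean-slab matching biases the
  recovered tilt by about a degree;
* the optimisation runs on the smooth trilinear objective (well-behaved
  basin), preceded by a half-resolution pyramid pass;
* the **metric of record** — the trace and `final_C` — is evaluated
  against the nearest-neighbour-resampled mask slab, exactly what
  `apply_pose()` returns for masks, so a perfectly registered pair scores
  C ≈ 1 instead of saturating at the antialiasing ceiling (~0.98).

`register_affine2d()` (for shrinkage) maximises a soft Dice overlap over
scale/rotation/shear/translation, initialised from centroids and
principal-axis moments; only per-axis scale factors are interpreted, which
is why an affine rather than a free-form model suffices.

### Quantification

* BI = 100 × bone / ROI-void: the denominator excludes the titanium
  cross-section so a fully filled pore space reads 100 % (a mode with the
  titanium included is available for sensitivity analysis).
* BC = 100 × covered / total scaffold-surface elements, where a surface
  element is a scaffold voxel inside the ROI with a face neighbour that is
  non-scaffold and also inside the ROI — the implant surface *facing the
  defect*; coverage means bone within a one-voxel face-adjacency band
  (city-block metric, resolution-stable and brute-force checkable).
* Shrinkage is reported both as the cortical-bone area ratio and as the
  product of the affine scale factors, each also expressed as
  100 − ratio; on pure affine deformations the two agree to within two
  points.
* `bi_profile()` gives the edge-to-edge per-slice BI; the 3D BI is exactly
  its void-weighted mean (an identity the tests assert).
* `orientation_sampled_estimate()` re-measures after random in-plane grid
  rotations (mean ± SD over, e.g., five orientations) — an interpretation
  of manual grid-based re-measurement protocols, flagged as such.
* `compare_groups()` enumerates the exact two-sided Mann--Whitney null for
  groups of up to 8 (ties handled exactly; the p-value sums arrangements
  at least as extreme as observed, point probability included) and falls
  back to the tie-corrected normal approximation; and
  `regression_with_band()` is OLS with the pointwise t-based 95 % band.

### Validation harness

`validate_registration()` replays the three accuracy experiments on a
bare-scaffold phantom scanned twice with independent noise: registering a
section numerically extracted from the *segmented* repeat scan
(repeat-scan noise), the same section resampled at 2.5/4.5/9 µm pixels
(resolution), and the section mask anisotropically shrunk in-plane
(cutting distortion — here the titanium itself deforms, because the
physical experiment cut a bare implant with a saw; in `simulate_histology`
the titanium stays rigid because in vivo only the tissue deforms).
Registration refines from a deliberately perturbed pose so each scenario
isolates its own similarity loss; global search robustness is covered by
`registration_accuracy_trials()`, which runs the full coarse-plus-refine
pipeline over ≥ 20 random oblique poses on the default phantom.

## What a green test does and does not establish

The synthetic world reproduces the *geometry* and the *failure modes* that
drive the method: a periodic-but-rough fiducial, metal streaks, blur and
noise, slab-thickness averaging, anisotropic tissue shrinkage, interface
separation, stain colouring.  It does not attempt realistic stain
chemistry, projection-domain CT physics, biological spatial statistics of
new bone (the fill model is a stand-in, not a claim), or free-form tissue
deformation.  Green acceptance therefore establishes that the algorithms
recover known ground truth under the stated distortions at desk scale —
not that any particular in-vivo number is reproduced; the published
in-vivo table depends on the animals and is explicitly out of scope.

## Degenerate inputs and tie-breaks

Constant images are rejected by the correlation metric and the histogram
tools (undefined denominators/quantiles); blank histology fields return
empty masks rather than erroring; slab planes outside the volume sample a
background value, while a pose whose centre leaves the volume errors.
Coarse-search ties break by offset, then angles.  Component despeckling
keeps anything at least half a strut cross-section, and always the largest
component.  All simulators are bit-reproducible for a fixed seed, with
per-call seeds derived by fixed offsets from one base seed.

## Known limitations

* The registration similarity ceiling is set by boundary discretisation of
  the two independently segmented masks (~0.97 with the trilinear metric
  at 9 µm); the nearest-neighbour metric of record removes the ceiling but
  is piecewise constant, hence used only for the final polish.
* BC depends on the contact-band convention; only the one-voxel band is
  pinned by construction, and the perimeter-length alternative is not
  implemented.
* The affine shrinkage model cannot represent spatially varying shrink;
  the area-ratio variant partially compensates, and the two variants'
  disagreement is itself a useful diagnostic.
* At histology shrink factors below ~0.9 the shrunk cortex can slide under
  the implant rim and be occluded by the opaque titanium, biasing the
  area-ratio variant low — a real effect of coaxial geometry, mitigated by
  the soft-tissue gap in the phantom but not eliminated.
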