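# scafreg

Correlative micro-CT / histology registration and bone histomorphometry
for additive-manufactured porous titanium implants.

## What problem this solves, and for whom

Bone researchers quantify how well bone grows into a porous metal scaffold
with two complementary modalities: stained ground-section histology (high
resolution, single 50–80 µm plane, tissue shrinks and tears during
processing) and micro-CT (whole volume, lower resolution, metal artefacts
around titanium). Comparing them requires knowing *where* the histology
section lies inside the CT volume. Because the titanium lattice does not
deform during histology processing, it can serve as a rigid fiducial: the
scaffold segmented from the 2D section is registered into the scaffold
segmented from the 3D volume, independently of the surrounding tissue.

`scafreg` implements that whole workflow in R:

* a ground-truthed **synthetic phantom world** (lattice scaffold with
  as-built strut roughness, implanted-tibia labels, forward micro-CT
  simulator with metal streaks, histology simulator with shrinkage and
  interface separation) so every stage is testable without animal data;
* micro-CT **preprocessing** (histogram normalisation, Perona–Malik
  anisotropic diffusion, calibrated global thresholding, metal-artefact
  compensation);
* **segmentation** of titanium and bone from CT volumes and RGB histology;
* coarse-to-fine **slice-to-volume rigid registration** driven by the
  correlation coefficient

  `C = Σ(Tᵢ−Tₘ)(Rᵢ−Rₘ) / ( √Σ(Tᵢ−Tₘ)² · √Σ(Rᵢ−Rₘ)² )`,

  with 3 or 6 degrees of freedom depending on section thickness, plus a
  2D affine registration for shrinkage estimation;
* **histomorphometry**: bone ingrowth `BI = 100·bone/ROI-void`,
  bone–implant contact `BC = 100·covered/total scaffold surface`,
  shrinkage (cortical area ratio and scale-factor product), edge-to-edge
  BI profiles, random-orientation re-measurement, exact small-sample
  Mann–Whitney tests and regression with a 95 % confidence band;
* a **validation harness** replaying the repeat-noise / resolution /
  cutting-distortion accuracy experiments, and an end-to-end accuracy
  driver over ≥ 20 random section poses;
* **I/O and a CLI**: MHD/RAW, NRRD, multi-page TIFF volumes, PNG/TIFF
  sections with JSON spacing sidecars; `phantom`, `segment`, `register`,
  `quantify`, `validate`, `convert` subcommands over one YAML config with
  provenance JSON for every run.

## Worked example

```r
library(scafreg)

# 1. the world: a 3 mm scaffold, an implanted tibia, one CT scan
design <- scaffold_design()          # Ø 3 mm x 1.8 mm, 180 um struts, 9 um voxels
scaf   <- make_scaffold(design)
round(100 * scaf$porosity, 2)        # 64.70  (design target 65 %)
round(100 * analytic_scaffold_porosity(design), 2)  # 65.17 (analytic oracle)

ph <- make_tibia_phantom(scaf, fill_fraction = 0.5, edge_bias = 1, seed = 1)
ct <- simulate_ct(ph$labels, ct_sim_params(noise_sd = 10, seed = 2))
vmask <- segment_titanium_ct(ct, threshold = "peak_average")

# 2. a histology section at an unknown oblique pose
pose <- rigid_pose(c(143, 7, -4), c(20, -35, 180), thickness_um = 60)
h <- simulate_histology(ph$labels, pose,
       histology_sim_params(60, shrink_x = 0.92, shrink_y = 0.92,
                            separation_um = 30, seed = 3))
smask <- segment_titanium_histology(h$image)

# 3. register it back into the volume
cand <- coarse_search(smask, vmask, search_grid(), thickness_um = 60)
fit  <- refine_rigid(smask, vmask, attr(cand, "poses")[[1]], thickness_um = 60)
fit
#> registration_result: final C = 0.9664 after 150 evaluations (6 DOF)
#> rigid_pose: euler ZYX (deg) = [142.999, 6.988, -4.003], t (um) = [20.02, -35.03, 180.01], thickness = 60.0 um
pose_difference(fit$pose, pose)
#> $rotation_deg   0.0121
#> $translation_um 0.037      # 0.004 voxel

# 4. quantify on the registered correspondence
tr <- ph$truth
bone_ingrowth(tr$bone_mask, tr$voi_mask, tr$scaffold_mask)  # 50    (= truth)
bone_contact(tr$bone_mask, tr$scaffold_mask, tr$voi_mask)   # 50.76 (= truth)
```

The printed final `C` is the correlation between the section's titanium
mask and the registered 2D correspondence resampled from the volume mask;
the recovered pose differs from the (here known) truth by well under a
voxel and a tenth of a degree — at in-vivo noise and deformation levels
the published workflow converged near `C ≈ 0.85`, which is the acceptance
bound used here.

## Command-line use

```sh
Rscript inst/cli/scafreg phantom  --config cfg.yaml --out out/ --seed 7
Rscript inst/cli/scafreg segment  --config cfg.yaml --in out/ct.mhd --out seg/
Rscript inst/cli/scafreg validate --config cfg.yaml --out val/
```

Every run writes `provenance.json` (parameters, seeds, versions, input
checksums). A YAML config overrides any subset of `default_config()`.

## Package layout

`R/` phantom, filters, segment, register, quantify, validate, stats, io,
cli modules; `src/` compiled kernels (slab resampling, diffusion, blur,
connected components, chamfer distance, banded median, 2D warps);
`vignettes/correlative-registration.Rmd` the methods vignette;
`tests/testthat/` unit, property and acceptance suites.
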