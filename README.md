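# shapefilt

Topology-preserving surface generation and deformation-based filtering for
subcortical and ventricular brain structures, in R.

Shape analysis of structures such as the hippocampus, putamen or lateral
ventricle starts from a binary voxel segmentation and needs a smooth,
topologically correct triangle mesh of the boundary. Extracting that mesh
directly (marching cubes) is faithful to the segmentation but inherits its
noise: staircase roughness, holes, disconnected islands, and lost thin
subregions (for the lateral ventricle, the thin bridge to the inferior
horn). `shapefilt` instead deforms a single smooth, topologically correct
**template** surface onto each subject's raw surface:

1. **Extract** the raw surface of the binary mask with marching tetrahedra
   on the Kuhn grid subdivision (watertight, no ambiguous cases).
2. **Rigidly align** the template to it by alternating Gaussian soft
   assignment `a_ij ∝ exp(−‖R s_i + t − d_j‖²/T)` with closed-form weighted
   Procrustes solves under geometric annealing of `T` (rotation +
   translation only, reflections excluded).
3. **Deform** the aligned template onto the raw surface with currents-based
   LDDMM: minimize `γ·Reg(α) + ‖[φ₁(template)] − [target]‖²_W` over
   per-vertex momenta, where surfaces are compared as currents (face
   centroids + area-weighted normals in a Gaussian RKHS at scale σ_W) and
   the flow is the forward-Euler integration of a σ_V-smooth velocity
   field. Analytic adjoint gradients, deterministic line-search descent.
4. **Voxelize** the deformed surface (strict inside test by parity ray
   casting) to obtain the filtered segmentation.

Because the deformed mesh reuses the template's faces verbatim, its Euler
characteristic and component count are exactly the template's; smoothness
is inherited from the template through the smooth flow.

Also included: evaluation metrics — Dice coefficient (DSC), absolute volume
difference (AVD), Pearson correlation (PCC), and the Geometric Laplacian
roughness score `GL(v) = v − Σ l_i⁻¹ v_i / Σ l_i⁻¹` summed over vertices —
IQR outlier QC (both the as-printed Q1-anchored rule and the Tukey fence),
Welch t-tests, CAP scores, NIfTI-1 and VTK/PLY/OFF I/O, and a seeded
phantom generator (ellipsoid, bent tube, and two-lobe bridge shapes with
controllable segmentation noise) so the whole pipeline is testable without
MRI data.

## Worked example

```r
library(shapefilt)

spec  <- phantom_spec("ellipsoid")              # 12 x 8 x 6 mm blob, 1 mm grid
truth <- make_phantom(spec)                     # noise-free ground truth
noisy <- corrupt_mask(truth, noise_spec(boundary_flip_rate = 0.05,
                                        n_holes = 3, seed = 11))
tpl   <- delaunay_template_mesh(truth)          # smooth template surface
res   <- filter_structure(noisy, tpl,
                          pipeline_config(opt = lddmm_control(max_iter = 60,
                                                              rel_tol = 1e-5)))
res
#> <filter_result> DSC(raw, filtered)=0.9494, AVD=0.007975,
#>     GL raw=698.02 -> filtered=69.13
```

The filtered surface overlaps the noisy input segmentation at DSC 0.95
while being ten times smoother (Geometric Laplacian 698 → 69), and the
filtered segmentation is *closer to the noise-free truth* than the noisy
input was:

```r
dsc(noisy, truth)              #> 0.959
dsc(res$filtered_mask, truth)  #> 0.990
```

On a severed two-lobe bridge phantom (the ventricle stress case) the raw
mask has 2 connected components; the filtered surface and its voxelization
have exactly 1, with Euler characteristic 2 — the template's topology.

A command-line interface over the same functions lives at
`inst/cli/shapefilt.R`
(`Rscript inst/cli/shapefilt.R filter --mask m.nii.gz --template tpl.vtk ...`,
with subcommands `extract`, `rigid`, `lddmm`, `filter`, `filter-batch`,
`metrics`, `qc`, `simulate`).

## Acceptance script

`scripts/acceptance.R` re-runs the complete pipeline from scratch on a
seeded phantom cohort — generation, corruption, template construction,
rigid + LDDMM filtering, voxelization and metrics — and writes its JSON
report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Vignette

`vignettes/shape-filtering.Rmd` documents the models and assumptions of
each stage, the tunable parameters and their defaults, what the phantom
generator does and does not emulate, and the package's numerical choices.
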