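# brainshiftr

Physics-based non-rigid registration for intra-operative brain-shift
compensation, in pure R.

During brain-tumor resection the brain deforms ("brain shift"), so the
pre-operative MRI — and everything registered to it — no longer matches
the patient. Given a pre-operative (floating) and an intra-operative
(fixed) volume, `brainshiftr` estimates a dense deformation field by
combining:

* **block matching** — exhaustive normalized-cross-correlation search for
  sparse displacements `D` with confidence weights `S` at
  high-variance registration points;
* a **linear-elastic tetrahedral FEM** of the brain (BCC image-to-mesh
  conversion; two-tissue material model, parenchyma E = 3000 Pa, ν = 0.45,
  ventricle E = 10 Pa, ν = 0.1) solving
  `[K + H'SH] U = H'S D + F`, where iterating the stress-relaxation force
  `F ← K U` moves from an outlier-tolerant approximation toward the
  interpolation solution;
* three **outlier-rejection schemes**:
  * `pbnrr_register()` — iteratively rejects the `floor(N·f_R/n_R)`
    matches with the largest block error `ξ_k = ‖(HU)_k − d_k‖` per
    iteration (point outliers);
  * `nemnrr_register()` — nested expectation-maximization over
    displacement, fuzzy edge-point correspondence, and a face-connected
    resection submesh `M_Rem` grown from tetrahedra whose displaced
    volume falls in the image background (element outliers);
  * `anrr_register()` — adaptive incremental warping with remeshing so no
    accepted mesh contains inverted or sliver elements (geometric
    outliers), plus registration-point-aware isotropic and anisotropic
    (Khachiyan minimum-volume-ellipsoid) mesh-sizing metrics.

Evaluation uses the Canny/Hausdorff protocol: edge point sets from the
warped floating and the fixed volume, compared by symmetric Hausdorff
distance, with the improvement ratio `(HD_before − HD_after)/HD_before`.

A synthetic phantom generator (`make_phantom()`) produces pre/intra pairs
with known ground-truth deformation and optional resection cavities, so
the whole stack is testable without clinical data.

## Worked example

```r
library(brainshiftr)

ph   <- make_phantom(phantom_spec(seed = 11))        # 64^3, 3 mm bump
mesh <- bcc_mesh_from_labels(ph$labels, 6)           # BCC mesh, 6 mm edge
res  <- pbnrr_register(ph$pre, ph$intra, mesh)
res
#> <registration_result> 770 vertices, 3557 active / 1180 rejected matches,
#>   max |U| = 5.702 mm, converged: FALSE

truth_fwd <- invert_field(ph$truth)                  # forward ground truth
tv  <- sample_trilinear(truth_fwd, mesh$vertices)
c(before = mean(sqrt(rowSums(tv^2))),
  after  = mean(sqrt(rowSums((res$U - tv)^2))))
#>    before     after
#> 1.6543724 0.6342222
```

The phantom's deformation displaces mesh vertices by 1.65 mm on average;
after registration the mean vertex error drops to 0.63 mm (sub-voxel —
the floor is set by integer-voxel matching — a 62% reduction). The
Canny/Hausdorff protocol can also be run, though note that at this desk
scale the symmetric HD is a max statistic sitting at the 1–2-voxel
edge-detection jitter floor, so it is not a sensitive measure of this
already-small deformation:

```r
rep <- evaluate_registration(ph$pre, ph$intra, res$dense_field)
rep
#> <eval_report> HD before 3.162 mm, after 3.742 mm, improvement -0.183
```

With a resected phantom, NEMNRR also recovers the cavity:

```r
ph2  <- make_phantom(phantom_spec(seed = 11,
          resection = list(center = c(42, 36, 34), radius = 8)))
res2 <- nemnrr_register(ph2$pre, ph2$intra, mesh)
length(res2$m_rem)                    # tetrahedra collected into M_Rem
#> [1] 106
sum(tet_signed_volumes(mesh$vertices, mesh$tets[res2$m_rem, ]))
#> [1] 1908   # mm^3, vs. 2145 mm^3 for the 8 mm sphere (11% low)
```

## Command line

```sh
inst/cli/brainshiftr phantom  --out work --size 64 --seed 7
inst/cli/brainshiftr register --method pbnrr \
    --floating work/pre.nii.gz --fixed work/intra.nii.gz \
    --labels work/labels.nii.gz --out work/reg
inst/cli/brainshiftr evaluate --pre work/pre.nii.gz \
    --intra work/intra.nii.gz --field work/reg/field.nii.gz \
    --out work/report.json
```

Subcommands: `phantom`, `features`, `match`, `register`
(`--method pbnrr|nemnrr|anrr`), `evaluate`, `sizing`. Every run writes its
resolved configuration for reproducibility.

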