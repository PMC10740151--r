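---
title: "Physics-based brain-shift registration: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physics-based brain-shift registration: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

During neurosurgical tumor resection, opening the skull and dura, drainage
of cerebrospinal fluid, gravity, and the removal of tissue itself deform
the brain by up to centimeters ("brain shift"). Pre-operative images — and
everything aligned to them, such as functional maps and tractography — are
then misaligned with the patient. Intra-operative MRI (iMRI) shows the
deformed configuration, and non-rigid registration of the pre-operative
(floating) volume to the iMRI (fixed) volume restores guidance.

`brainshiftr` implements a physics-based approach: sparse displacements
measured by block matching are regularized by a linear-elastic tetrahedral
finite-element (FE) model of the brain, with three outlier-rejection
schemes layered on top:

* **PBNRR** — iterative rejection of *point* outliers (bad matches);
* **NEMNRR** — nested expectation-maximization that additionally collects
  *element* outliers (tetrahedra lying in resected tissue) into a growing
  face-connected submesh `M_Rem`;
* **ANRR** — adaptive incremental warping with remeshing, eliminating
  *geometric* element outliers (slivers, inverted tetrahedra) caused by
  large deformations.

## The core model

Registration points are voxels of the floating image whose local intensity
variance (over a block of half-width `B`, default `[1,1,1]`) is in the top
`selection_fraction` (default 0.05) of candidates. At each point, the
displacement is found by exhaustive normalized-cross-correlation (NCC)
search over all integer-voxel offsets within a window of half-width `W`
(default `[5,5,5]`; `prod(2W+1)` = 1331 candidates), an
`O(BxByBz × WxWyWz)` search per point. The best NCC (clamped to `[0,1]`)
becomes the match's confidence weight, the diagonal of the match
stiffness `S`.

The displacement field is the piecewise-linear interpolant of vertex
displacements `U` on a tetrahedral mesh built from the segmented brain by
body-centered-cubic (BCC) lattice subdivision. `U` balances the elastic
energy of the mesh against the weighted match residuals:

```
[K + H' S H] U = H' S D + F
```

where `K` is the assembled linear-elasticity stiffness matrix (P1
tetrahedra, engineering-strain Voigt form), `H` interpolates vertex
displacements to match locations via barycentric weights, `D` stacks the
block-matching displacements, and `F` is an external force. With `F = 0`
this is an *approximation* (outlier-tolerant but biased); iterating
`F ← K U` relaxes the internal stress and converges to the
*interpolation* solution that fits the retained matches exactly. PBNRR
interleaves this relaxation with rejection: for `n_R` iterations (default
10) it discards the `floor(N f_R / n_R)` matches with the largest block
error `ξ_k = ‖(H U)_k − d_k‖₂` (with `N` fixed at the initial located
count — this reproduces the published rejection totals exactly), then
relaxes for up to `n_A` further steps (default 10) or until the maximum
vertex change drops below `tol` (default 1e-3 mm).

Materials follow the two-tissue brain model: parenchyma (and tumor)
`E = 3000 Pa, ν = 0.45`; ventricle `E = 10 Pa, ν = 0.1`. Only relative
stiffness matters to the solution up to the global scale discussed below.

## Displacement conventions

Two conventions coexist and are easy to conflate:

* the solvers estimate **forward** displacements (`U`, at mesh vertices in
  floating-image space): where material moves *to*;
* images are resampled by **backward (pull)** warping:
  `out(v) = in(world(v) + field(v))` — `warp_image()` takes pull fields,
  and the phantom's ground truth is stored in this convention so that
  `intra = warp_image(pre, truth)` holds exactly.

`invert_field()` converts between the two by damped fixed-point iteration
(`T'(x) = −T(x + T'(x))`), and `registration_result$dense_field` is always
the pull field ready for `warp_image()`, while `forward_field` is the
rasterized forward field. Tests compare `U` against the *inverted* truth
sampled at vertices.

## The stiffness scale

The published formulation leaves the relative scale of `K` (units of
Pa·mm) and `H'SH` (dimensionless NCC weights) open. We measured, on the
default phantom, that the strain and match energy terms end up within a
factor ~3 of each other at the solution for *any* scale across three
orders of magnitude, because stress relaxation restores data fidelity
regardless. What the scale does control is the *rejection phase*: if the
mesh is too soft, outlier matches bend the model locally, their block
error looks small, and the rejection ranking degenerates (planted-outlier
hit rate 0.15 vs 0.90 in our experiments). The default
`k_scale = "auto"` therefore sets `100 × trace(H'SH)/trace(K)` — stiff
enough that outliers cannot hide, with fidelity recovered by relaxation.

## NEMNRR

NEMNRR extends the cost to three variables — displacement `U`, fuzzy
point correspondence `C`, and the resection submesh `M_Rem`:

```
J(U, C, M_Rem) = Σ_{e∉M_Rem} U' K_e U
              + λ1 Σ_i w_i ‖(H U)_i − D(C)_i‖²
              + λ2 Σ_{e∈M_Rem} V_e
```

with `D(C)_i = Σ_j c_ij t_j − s_i` the displacement from source point
`s_i` to its fuzzy target barycenter (targets `t_j` are Canny edge points
of the fixed image). The inner EM alternates a Gaussian soft assignment
(`c_ij ∝ exp(−‖s_i + (HU)_i − t_j‖²/τ²)` over candidates within
`candidate_radius`) with the linear M-step solve on `M \ M_Rem`; the
outer loop detects tetrahedra whose displaced volume lies in the
background image (BGI, intensity below a recursive-Otsu threshold) and
grows `M_Rem` by face connectivity, monotonically, as a single connected
component.

Three implementation choices deserve emphasis, all made after studying the
optimizer's behaviour on synthetic data:

1. **Initialization and W.** Block matching is run first; its confidences
   are the weights `W` and a stiff approximation solve initializes `U`.
   Without this, the EM must pull the mesh several millimeters through a
   dense cloud of edge points and instead wanders.
2. **Short inner EM.** With dense targets, the fuzzy-correspondence update
   is a mean-shift flow toward edge-density modes: run to a fixed point it
   *degrades* a good initialization monotonically. The inner EM is
   therefore a short refinement (`inner_max = 3`). Related: the soft
   E-step minimizes the EM free energy, not `J` itself, so `J` is only
   guaranteed non-increasing across M-steps (which the tests assert); the
   full `J` history is recorded as a diagnostic.
3. **Volumetric BGI test.** An element "falls in" the background when the
   majority of 15 interior sample points (nearest-neighbour sampled, to
   avoid the half-intensity blend at the cavity wall) are below threshold,
   and a new `M_Rem` seed must reach `min_seed_volume` (default 500 mm³ —
   resection cavities are cm³-scale) so single dark elements from noise
   never start a bogus resection region.

## ANRR

ANRR splits the deformation into `n_inc` increments (default 5). Each
increment re-meshes the current warped segmentation (with the package's
own BCC mesher — the external Delaunay and MMG3D adapters are out of
scope; a metric-field export in the MEDIT `.sol` dialect is provided
instead), runs one PBNRR pass against the fixed image, accepts
`1/(remaining increments)` of the solved field, verifies that the
deformed mesh has no inverted elements and no dihedral below
`sliver_dihedral_deg` (default 5°), and composes the accepted pull field
into the cumulative one. On a quality failure the accepted fraction is
halved (keeping per-increment deformation small relative to the elements
is precisely the idea of incremental warping) before the lattice is
refined; a persistent failure is an error naming the increment.

The registration-point-aware sizing metrics: `isotropic_sizing()` sets
each vertex's spacing to the distance of its k-th closest registration
point, so a conforming mesh holds ≈ k points per vertex cell complex;
`anisotropic_metric()` reflects the k nearest points through the vertex,
encloses the 2k points in a minimum-volume ellipsoid (Khachiyan's
algorithm; the reflected set is centrally symmetric, so the
origin-centered variant is used and the center is exact), and inflates
all semi-axes by the constant `a` — exactly multiplicative, as the tests
verify for `a ∈ {1.0, 1.2, 1.5}`.

## Evaluation

`evaluate_registration()` implements the Canny/Hausdorff protocol: edge
point sets from the (warped) floating and the fixed volumes, compared by
the symmetric Hausdorff distance in world millimetres (voxel-space
distances would be distorted by anisotropic spacing), plus the
improvement ratio `(before − after)/before`. The HD is an upper bound on
the misalignment and knows nothing about correspondence;
correspondence-aware error remains an open problem upstream and is out of
scope here.

## The synthetic phantom — what it does and does not establish

`make_phantom()` builds a textured ellipsoidal brain (with ventricle,
tumor, and random internal "structures" emulating the edges that gyri and
deep gray matter provide in real scans), a smooth fold-free ground-truth
deformation, and the warped, optionally resected, noisy intra-operative
image. Key default choices:

* **Deformation**: one Gaussian bump, amplitude 3 mm, width 20 mm —
  brain-scale, like a gravity-induced sag. A much narrower bump would
  leave the surface motion everywhere sub-voxel, unresolvable *in
  principle* by integer-voxel block matching.
* **Decay shell**: the truth field is full-strength throughout the brain
  (the cortical surface is what shifts) and decays to zero in a shell
  *outside* the brain mask.
* **Texture**: correlation length ≈ 2 voxels, sd = 40% of local tissue
  intensity. NCC needs this variability; a smooth untextured surface is
  self-similar and produces tangential "aperture" slips of several mm.
  Texture scales with tissue brightness and intensities are clamped to
  [25, 250], so tissue never reaches the air background — as in real MRI.
* **Noise**: additive σ = 1 intensity unit on the intra image.

A green phantom test establishes that the pipeline recovers a smooth,
moderate, known deformation from realistic-contrast images and that the
outlier machinery isolates planted corruption and synthetic cavities. It
does *not* establish clinical accuracy: real brains have far richer
anatomy, pathology-dependent intensity changes, imaging artifacts, and
deformations that are not single smooth bumps. The published clinical
error tables are inputs we can check only for their arithmetic
(rejection counts, improvement ratios), not reproduce.

## Numerical details

* Voxel indices are 0-based; `world = origin + v ∘ spacing` with a
  diagonal direction matrix only (no oblique orientations).
* Block-matching ties break toward the smallest displacement norm, then
  lexicographic offset; variance-ranking ties break by voxel index;
  point-in-tet ties go to the lowest tet id — everything is deterministic.
* No Dirichlet boundary conditions: well-posedness comes from `H'SH`;
  rank deficiency (matches that do not constrain all six rigid modes) is
  reported as an error, never silently regularized.
* Khachiyan tolerance defaults to 1e-4 (general) / 1e-6 (per-vertex
  metrics) with a 10,000-iteration cap; degenerate (coplanar) inputs are
  an error for the general routine and an isotropic fallback (recorded)
  for the per-vertex metric.
* Field inversion uses 10 fixed-point iterations; the contraction rate is
  the displacement-gradient norm, ≪ 1 for brain-shift-scale fields.

## Known limitations

* Integer-voxel matching bounds accuracy at ~half a voxel; no sub-voxel
  refinement is attempted (out of scope).
* The scalar NCC confidence weights S are isotropic; the tensor
  (direction-dependent) weighting of the original formulation is out of
  scope, which makes flat-edge aperture errors rejectable but not
  correctable.
* Meshes are BCC-only; adapted anisotropic meshes require exporting the
  metric field to an external mesher.
* The NEMNRR inner EM is a short refinement, not a convergent
  optimization of `J` (see above); on images without reliable block
  matches it would inherit block matching's failures.
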