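---
title: "Methods: voxel finite-element analysis of microfracture hole spacing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel finite-element analysis of microfracture hole spacing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(subchondralFE)
```

## The question and the model

Microfracture surgery perforates the subchondral bone plate — the thin
dense bone layer under the articular cartilage — so that marrow stem cells
can reach a cartilage defect. Tighter hole spacing recruits more cells but
removes more load-bearing bone. This package quantifies the mechanical
side of that trade-off: how does the distance between holes change the
peak stress in the plate under physiological compression?

The model is deliberately simplified and laterally generic rather than
anatomic: a rectangular osteochondral block of two homogeneous isotropic
linear-elastic layers,

* subchondral plate: thickness 0.3 mm, E = 17 GPa, ν = 0.3, yield stress
  135 MPa;
* trabecular bone (homogenised): thickness 7.7 mm, E = 700 MPa, ν = 0.3.

The cartilage layer is omitted: the quantity of interest is the bone
stress near the holes, and cartilage mainly redistributes the contact
load, which we parameterise directly through the load footprint. The
literature is split between 0.25 and 0.3 for the trabecular Poisson's
ratio; we default to 0.3 and expose the value through
`trabecular_bone_material(poisson_ratio = )`.

Holes are vertical cylinders drilled from the articular surface, 4 mm
deep, so each hole fully perforates the plate and enters the trabecular
bed. Spacings of 1, 1.5, 2, 2.5, 3, 4 and 5 mm plus an intact control form
the eight study configurations (`make_paper_configs()`).

## Parameters the experiment leaves open

Several geometric quantities needed by any concrete model are not fixed by
the clinical description of the procedure. The package chooses defaults
once, documents them here, embeds them in every output file (the
assumptions ledger), and treats them as configuration, not constants:

* **Hole diameter** — 1.0 mm, the scale of a microfracture awl tip, and
  compatible with a 1 mm spacing.
* **Spacing convention** — "distance between holes" is read as
  *edge-to-edge* (so 1 mm spacing with 1 mm holes gives a 2 mm pitch and a
  geometrically valid pattern); centre-to-centre is available via
  `hole_pattern(spacing_convention = "center_to_center")`.
* **Hole layout** — holes sit on a maximal centred square grid whose
  *centres* lie within the defect rectangle; hole walls may overhang the
  defect by up to one radius (the walls must still clear the block
  boundary, which is enforced). This convention makes the emergent hole
  counts (25, 16, 9, 9, 9, 4, 4 across the seven spacings on the default
  8 × 8 mm defect) consistent with exhaustive packing enumeration. A
  hexagonal layout is also provided.
* **Defect and block extents** — an 8 × 8 mm defect centred in a
  16 × 16 mm block: a clinically plausible lesion with a ≥ 4 mm margin so
  the lateral boundary does not interact with the hole field.
* **Load transfer** — the donor experiment describes a rounded femoral
  block contacting a flat tibial block through frictionless contact.
  Resolving two-body contact adds machinery without changing the
  transmitted resultant, which is what drives plate stress; we therefore
  replace contact with a statically determinate downward traction carrying
  the full 147 N on the articular face. Three footprints are offered:
  uniform over the whole face (default), uniform over a circular patch,
  and a Hertzian profile `p(r) = p0 √(1 − r²/a²)` over a patch. The
  footprint controls absolute stress levels far more than hole spacing
  does, which is why reported magnitudes are comparable to published
  per-group values only as bounds, never MPa-for-MPa.

## Discretisation

The parametric geometry is rasterised onto a regular voxel grid
(`voxelize()`): each voxel takes the region of its centroid
(plate/trabecular/void), a deterministic rule that avoids volume-fraction
thresholds. Grid dimensions are `ceiling(extent/voxel)` with the realised
voxel size stretched so the grid covers the block exactly. Voxels may be
anisotropic: the default "fast" preset uses 0.4 mm lateral × 0.15 mm
vertical voxels so the 0.3 mm plate always carries two element layers
without exploding lateral counts; the "paper" preset (0.1 mm isotropic,
~2M elements) exists for workstation-scale runs and is not used by the
test or acceptance workloads, which run at the fast preset (~86k elements,
~277k degrees of freedom).

Two resolution rules are enforced: at least two elements through the
plate (hard error — a single element through a bending plate is
meaningless), and at least two lateral elements per hole diameter (error),
with a warning below four because hole walls are then coarsely resolved.
At the fast preset the 1 mm holes sit at 2.5 elements per diameter: the
jagged-wall discretisation error this causes is precisely what the
convergence study (`convergence_study()`) and the robust 99.9th-percentile
peak are there to quantify.

Each solid voxel becomes an 8-node trilinear hexahedron with full
2 × 2 × 2 Gauss quadrature. Shear locking of trilinear bricks at thin
structures is acknowledged; with ≥ 2 elements through the plate and
stress read at centroids the effect on the reported peaks is secondary to
the voxelisation error, and the patch, column and hole benchmarks below
bound the overall behaviour. The mesh builder rejects solid regions that
are not a single face-connected component (`mesh_discontinuity`): an
edge- or corner-connected pair of voxels would create a mechanism and a
singular stiffness matrix. This mirrors a real failure mode of
segmentation-derived models, reproduced deliberately by the phantom tests.

## Solver

The symmetric positive-definite system is solved two ways, chosen by
size: sparse Cholesky factorisation (through Matrix/CHOLMOD) below 15k
free DOFs, and diagonally preconditioned conjugate gradients above. The
Jacobi preconditioner neutralises the 24× stiffness contrast between
plate and trabecular rows; the fast-preset systems converge to the 1e-8
relative-residual default in ~600–700 iterations (~30 s each on one CPU).
DOF ordering is lexicographic in node index, so runs are bit-reproducible.
Every solve verifies its residual and the global reaction balance
(reactions at the fixed base must cancel the applied load to 1e-6
relative) before results are accepted.

Stress is recovered at element centroids only — no nodal averaging or
extrapolation — because centroid values are deterministic, cheap, and do
not smear the isolated spikes that voxel-jagged hole rims produce;
instead those spikes are reported alongside a robust statistic (the
99.9th percentile of plate von Mises) while the raw maximum remains the
headline number for comparability. The safety factor is peak/yield:
published per-group values match this ratio (e.g. 52.8/135 → 0.39,
71.8/135 → 0.53) even though the accompanying prose defines the factor
the other way around; the two printed values that do not match
(the 4 mm and 5 mm groups, apparently swapped) are flagged in the tests,
not corrected. The separately quoted mean factor of 0.41 is likewise
inconsistent with the printed per-group values and is not reproduced.

## Verification ladder

* **Patch test** — homogeneous ν = 0 block under uniform pressure with a
  vertical-roller base: σ_zz = −p at machine precision on every mesh
  (the exact solution lies in the trilinear space). The roller base is a
  test fixture; the study model uses the fully fixed base.
* **Two-layer column** — ν = 0 both layers, full 147 N: mean top-face
  displacement matches the series-spring closed form
  (F/A)(t_p/E_p + t_t/E_t) ≈ 6.3 µm to 0.1% at the fast preset (the
  residual is plate-thickness rasterisation, not solver error).
* **Plate with a hole (Kirsch)** — quarter-symmetric plane-strain slab
  with a circular through-hole under remote tension. The measured
  concentration factor (max centroid hoop stress on the transverse
  ligament / remote stress) reaches 2.61 at 0.4 mm voxels and 2.78 at
  0.2 mm against the analytic 3.0: 13% and 7% low, converging from below
  as centroid sampling approaches the hole wall. The benchmark geometry
  (radius 4 mm) gives ten voxels per radius at the fast lateral
  resolution — holes resolved more coarsely than that under-read their
  rim stresses accordingly, which is the main caveat on the study's
  absolute peaks.
* **Dense oracle** — on meshes of ≤ 8 elements the sparse assembly and
  solution are compared entry-wise (1e-8 relative) against an
  independent dense implementation with finite-difference shape
  gradients and 3 × 3 × 3 quadrature.
* **Properties** — six rigid-body modes per element and per assembled
  system, exact linearity in load and modulus, rotation invariance of
  von Mises under 100 random rotations, exact load-share bookkeeping.

## Synthetic micro-CT phantoms

The phantom module emulates the imaging provenance of the model: a fully
dense plate (17 slices at the 18 µm default voxel — `round(0.3/0.018)`)
over a trabecular region drawn as a Gaussian random field, smoothed to a
0.1 mm correlation length by periodic FFT convolution and thresholded at
the quantile that realises the target BV/TV (so the realised fraction
matches the target up to voxel-count discreteness, within ±0.02 across
seeds by construction), plus optional additive Gaussian noise. All
randomness derives from the stated seed and the caller's RNG state is
restored afterwards.

What the phantom does **not** claim: real trabecular architecture (plate/
rod morphology, anisotropy, cortical gradients), scanner physics (beam
hardening, partial-volume effects — scanner settings are recorded as
metadata only), or calibrated Hounsfield intensities. Its purpose is to
exercise the image → segmentation → layer labelling → mesh path,
including the plate/trabecular discontinuity that aggressive thresholding
produces; tests passing on phantoms therefore validate the pipeline's
mechanics, not its fidelity to any particular scanner or specimen.

## Numerical choices and degenerate inputs

* Solver tolerance 1e-8 (relative residual), PCG budget 20k iterations;
  non-convergence raises an error carrying the residual history.
* Peak ties break to the lowest element index; `quantile(type = 7)` for
  the robust peak.
* Empty load footprints, empty bottom node sets, inverted elements,
  unknown layer labels, non-positive yield stresses and disconnected
  solids all raise immediate errors rather than propagating NaNs.
* Reports are written without timestamps in the CSV so reruns are
  byte-identical; the JSON report carries the timestamp plus the
  assumptions ledger and the caveat block.

## Known limitations

Anatomy (condylar curvature, cartilage, meniscus) and two-body contact
are out of scope by design; absolute stress levels scale with the assumed
load footprint. Voxel meshes under-resolve hole rims at the fast preset
(quantified above). Material behaviour is linear elastic — no damage,
fatigue or awl-induced crushing, so conclusions hold only while the
surrounding bone is intact. The trabecular layer is homogenised;
per-trabecula stress concentrations are invisible at this scale.
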