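# subchondralFE

Voxel-based finite-element analysis of the subchondral bone plate after
microfracture surgery.

Microfracture treats cartilage defects by awl-drilling small holes through
the subchondral bone plate into the marrow space, recruiting mesenchymal
stem cells to the lesion. Drilling the holes closer together increases the
stem-cell supply — but every hole removes load-bearing bone, so the
clinical question is whether dense hole patterns compromise the structural
stability of the thin (≈0.3 mm) subchondral plate. `subchondralFE` answers
that question *in silico* for orthopaedic-biomechanics researchers: it
builds a parametric two-layer osteochondral block, drills hole patterns at
configurable spacings, solves the linear-elasticity problem, and reports
peak von Mises stress and safety factors against the plate yield stress.

## Model

The block is a 16 × 16 mm, 8 mm deep two-layer stack: a 0.3 mm dense
subchondral plate (E = 17 GPa, ν = 0.3, yield σ_y = 135 MPa) over 7.7 mm
of homogenised trabecular bone (E = 700 MPa, ν = 0.3). Vertical
cylindrical holes (diameter 1 mm, depth 4 mm) are laid out on a square
grid over a central 8 × 8 mm defect at edge-to-edge spacings of 1–5 mm. A
147 N compressive load (two-legged standing) is applied as a downward
traction on the articular surface; the base is fixed.

The geometry is rasterised to a voxel grid (mirroring micro-CT
provenance), each solid voxel becoming one 8-node trilinear hexahedral
element with full 2 × 2 × 2 Gauss quadrature. The discrete problem

K u = f,  σ = D B u,
σ_vm = √(½[(σxx−σyy)² + (σyy−σzz)² + (σzz−σxx)²] + 3(σxy² + σyz² + σzx²))

is solved by sparse Cholesky factorisation (small systems) or diagonally
preconditioned conjugate gradients (large systems) to a 1e-8 relative
residual. The per-configuration safety factor is σ_vm,peak / σ_y; in this
study's convention values **below 1** indicate a structurally safe plate.

A synthetic micro-CT phantom generator (dense plate over a thresholded
correlated Gaussian random field at 18 µm voxels, controlled BV/TV) plus
threshold segmentation and per-column layer labelling exercise the same
image → mesh → solve path that real scans would take, including the
plate/trabecular discontinuity failure mode that breaks structural
analysis when segmentation is too aggressive.

## Worked example

```r
library(subchondralFE)

ex <- run_paper_experiment(preset = "fast")  # ~4 min on one CPU
summary(ex)
```

```
  label spacing n_holes peak_vm_plate robust_peak_vm_plate peak_displacement safety_factor
 intact      NA       0         2.160                2.159          0.005884       0.01600
    1mm     1.0      25         2.612                2.612          0.006209       0.01935
  1.5mm     1.5      16         2.665                2.665          0.006142       0.01974
    2mm     2.0       9         2.778                2.778          0.006039       0.02058
  2.5mm     2.5       9         2.588                2.588          0.005997       0.01917
    3mm     3.0       9         2.588                2.588          0.005995       0.01917
    4mm     4.0       4         2.473                2.473          0.005933       0.01832
    5mm     5.0       4         2.509                2.509          0.005946       0.01858

max plate peak von Mises: 2.778 MPa ('2mm'); yield 135 MPa
all safety factors < 1: yes
```

Each row is one configuration: the hole count emerges from packing the
spacing into the defect, `peak_vm_plate` is the largest element-centroid
von Mises stress in the plate (MPa), `robust_peak_vm_plate` its 99.9th
percentile (guarding against voxel-rim spikes), `peak_displacement` the
largest nodal displacement magnitude (mm), and `safety_factor` the
peak-to-yield ratio. Under the package's default full-face traction the
plate stays far below yield in every configuration, and tightening the
spacing from 5 mm to 1 mm barely moves the peak stress — the
structural-stability conclusion. Absolute magnitudes depend strongly on
the assumed load footprint (a concentrated contact patch raises them;
see `load_case(application = "hertzian_patch")`).

Single configurations, phantoms and exports:

```r
fit <- fe_solve(model_config(hole_pattern = hole_pattern(spacing = 2)))
summary(fit); plot(fit)
write_vtk(fit$mesh, "stress.vtk",
          cell_data = list(von_mises = fit$stress$von_mises))

v <- generate_phantom(phantom_params(dims = c(64, 64, 64), seed = 1))
lab <- label_layers(segment_volume(v, 0.5), 0.3)
```

A thin CLI wrapper with `run` / `converge` / `phantom` / `export-vtk`
subcommands is installed at `inst/cli/bonefem`.

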