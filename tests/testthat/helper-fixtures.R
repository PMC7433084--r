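# Shared small fixtures, built in code.

# a small, quick two-layer block: 8 x 8 mm laterally, 0.3 + trab mm deep
small_stack <- function(nu = 0.3, trab = 2.7) {
  layer_stack(plate_thickness = 0.3, trabecular_thickness = trab,
              lateral_extent_x = 8, lateral_extent_y = 8,
              plate_material = material_spec("plate", 17000, nu, 135),
              trabecular_material = material_spec("trab", 700, nu))
}

small_config <- function(spacing = NULL, nu = 0.3, voxel_lateral = 0.5,
                         voxel_vertical = 0.15, force = 147, trab = 2.7) {
  pat <- if (is.null(spacing)) NULL else
    hole_pattern(spacing = spacing, hole_depth = 1,
                 defect_extent_x = 4, defect_extent_y = 4)
  model_config(layer_stack = small_stack(nu, trab), hole_pattern = pat,
               load_case = load_case(total_force = force),
               voxel_size_lateral = voxel_lateral,
               voxel_size_vertical = voxel_vertical,
               label = if (is.null(spacing)) "small_intact"
                       else sprintf("small_%gmm", spacing))
}

# fully solid labelled grid of given dims / voxel size
solid_grid <- function(dims, vs = c(1, 1, 1), label = 1L) {
  voxel_grid(array(label, dim = dims), vs, kind = "labels")
}

# tiny mesh (nx x ny x nz solid voxels) for oracle comparisons
tiny_mesh <- function(nx = 2, ny = 2, nz = 2, vs = c(1, 1, 1),
                      plate_layers = 0) {
  lab <- array(1L, dim = c(nx, ny, nz))
  if (plate_layers > 0) lab[, , seq_len(plate_layers)] <- 2L
  build_hex_mesh(voxel_grid(lab, vs, kind = "labels"))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)) / max(abs(expected), 1e-300), tol)
}
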