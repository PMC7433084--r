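# Closed-form verification problems for the element/solver stack.

#' Series-spring deflection of the two-layer column
#'
#' Closed form for the mean top-face displacement of the two-layer block
#' under a uniform axial traction with zero Poisson's ratio in both layers:
#' `(F/A) (t_p/E_p + t_t/E_t)`. With nu = 0 the trilinear element space
#' contains the exact solution, so the FE answer should match to solver
#' tolerance.
#'
#' @param stack A [layer_stack()].
#' @param total_force Axial force in N.
#' @return Displacement in mm.
#' @export
two_layer_column_deflection <- function(stack = layer_stack(),
                                        total_force = 147) {
  A <- stack$lateral_extent_x * stack$lateral_extent_y
  (total_force / A) * (
    stack$plate_thickness / stack$plate_material$young_modulus +
    stack$trabecular_thickness / stack$trabecular_material$young_modulus)
}

#' Plate-with-hole (Kirsch) stress-concentration benchmark
#'
#' Quarter-symmetric plane-strain model of an infinite plate with a
#' circular through-hole under remote uniaxial tension, meshed with one
#' layer of voxel hexahedra. Symmetry planes carry normal rollers, every
#' node is constrained to zero out-of-plane displacement (plane strain),
#' and the remote edge carries a uniform tension. The analytic
#' stress-concentration factor at the hole is 3 for the infinite plate;
#' the finite quarter-width raises it slightly (a few percent at the
#' default hole-to-width ratio).
#'
#' The reported factor is the maximum element-centroid hoop stress on the
#' transverse ligament (the row of elements just off the symmetry plane
#' through the hole centre, where the analytic peak sits) divided by the
#' remote stress. Centroid sampling reads the stress half an element away
#' from the hole wall, so the factor approaches 3 from below as the mesh
#' is refined.
#'
#' @param voxel_size Element size in mm.
#' @param hole_radius Hole radius in mm (default 4; ten voxels per radius
#'   at the fast-preset lateral resolution).
#' @param width Quarter-plate width in mm (default 24).
#' @param material A [material_spec()] (the factor is independent of E and
#'   only weakly dependent on nu through the discretisation).
#' @param remote_stress Remote tension in MPa (default 1).
#' @return List: `kt` (measured concentration factor), `kt_max` (max von
#'   Mises anywhere / remote, sensitive to voxel-corner spikes),
#'   `n_elements`, `voxel_size`.
#' @export
kirsch_benchmark <- function(voxel_size = 0.4, hole_radius = 4, width = 24,
                             material = material_spec("slab", 17000, 0.3),
                             remote_stress = 1) {
  stopifnot(voxel_size > 0, hole_radius > 0, width > 2 * hole_radius)
  n <- as.integer(ceiling(width / voxel_size - 1e-9))
  h <- width / n
  # solid where the voxel centroid is outside the quarter hole at (0, 0)
  xc <- (seq_len(n) - 0.5) * h
  solid2d <- outer(xc^2, xc^2, `+`) > hole_radius^2
  labels <- array(LABEL_BACKGROUND, dim = c(n, n, 1L))
  labels[, , 1][solid2d] <- LABEL_TRABECULAR
  grid <- voxel_grid(labels, c(h, h, h), kind = "labels")
  mesh <- build_hex_mesh(grid)
  sys <- assemble_system(mesh, materials = list(trabecular = material))
  nodes <- mesh$nodes
  tol <- h * 1e-6
  # symmetry rollers + plane strain
  cdof <- c(3L * (which(nodes[, 1] < tol) - 1L) + 1L,   # ux = 0 on x = 0
            3L * (which(nodes[, 2] < tol) - 1L) + 2L,   # uy = 0 on y = 0
            3L * seq_len(nrow(nodes)))                  # uz = 0 everywhere
  # uniform tension on the x = width face, tributary shares
  f <- numeric(sys$n_dofs)
  right <- which(nodes[, 1] > width - tol)
  edge <- nodes[right, 2] < tol | nodes[right, 2] > width - tol
  share <- ifelse(edge, 0.5, 1) # interior face nodes tributary h*h, edges half
  f[3L * (right - 1L) + 1L] <- remote_stress * h * h * share
  # rescale to the exact face resultant
  f <- f * (remote_stress * width * h) / sum(f)
  sys$constrained_dofs <- sort(unique(cdof))
  sys$load <- f
  disp <- solve_system(sys, tol = 1e-10)
  stress <- recover_stress(disp, mesh,
                           materials = list(trabecular = material))
  # ligament: the column of elements hugging the x = 0 symmetry plane,
  # which crosses the analytic hoop-stress peak just above the hole
  lig <- which(mesh$voxel_index[, 1] == 1L)
  kt <- max(stress$stress[lig, "sxx"]) / remote_stress
  list(kt = kt, kt_max = max(stress$von_mises) / remote_stress,
       n_elements = nrow(mesh$elements), voxel_size = h)
}

#' Homogeneous patch-test configuration
#'
#' Uniform pressure on a homogeneous zero-Poisson block with a vertical
#' roller base: the exact solution is a uniform uniaxial stress state
#' sigma_zz = -p, which the trilinear element reproduces to machine
#' precision on any mesh. Returns the solved result for inspection.
#'
#' @param pressure Applied pressure in MPa.
#' @param n Elements per edge of the cubic test block (>= 4, so both
#'   nominal layers of the homogeneous block keep two element layers).
#' @param young_modulus Modulus of the block, MPa.
#' @return An [fe_solve()]-like list with `stress`, `mesh`, `displacement`.
#' @export
patch_test <- function(pressure = 1, n = 4, young_modulus = 1000) {
  stopifnot(n >= 4)
  mat <- material_spec("patch", young_modulus, 0)
  st <- layer_stack(plate_thickness = 5, trabecular_thickness = 5,
                    lateral_extent_x = 10, lateral_extent_y = 10,
                    plate_material = mat, trabecular_material = mat)
  cfg <- model_config(layer_stack = st,
                      load_case = load_case(total_force = pressure * 100),
                      voxel_size_lateral = 10 / n,
                      voxel_size_vertical = 10 / n,
                      label = "patch")
  fe_solve(cfg, constraint = "roller_z")
}
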