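#' Solve one model configuration end to end
#'
#' The package's central entry point: voxelizes the parametric geometry,
#' builds the hexahedral mesh, assembles and solves the linear-elasticity
#' problem, recovers centroid stresses and summarises plate safety. The
#' whole chain is deterministic: identical configurations give bit-identical
#' results.
#'
#' @param config A [model_config()].
#' @param constraint Base constraint, `"fixed"` (the study model) or
#'   `"roller_z"` (verification fixture).
#' @param direct_limit Passed to [solve_system()].
#' @param verbose Print per-stage progress.
#' @return An object of class `fe_result` bundling the `config`, `mesh`,
#'   `node_sets`, `displacement`, `stress` and a one-row `report` data frame
#'   (label, spacing, n_holes, n_elements, n_nodes, peak_vm_plate,
#'   robust_peak_vm_plate, peak location, peak_displacement, safety_factor,
#'   yield_stress_used).
#' @examples
#' \donttest{
#' cfg <- model_config(label = "intact", voxel_size_lateral = 0.8,
#'                     voxel_size_vertical = 0.15,
#'                     layer_stack = layer_stack(lateral_extent_x = 8,
#'                                               lateral_extent_y = 8))
#' fit <- fe_solve(cfg)
#' summary(fit)
#' }
#' @export
fe_solve <- function(config, constraint = "fixed", direct_limit = 15000,
                     verbose = FALSE) {
  stopifnot(inherits(config, "model_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[3]
  grid <- voxelize(config)
  mesh <- build_hex_mesh(grid)
  say("[%s] mesh: %d elements, %d nodes (%.1fs)", config$label,
      nrow(mesh$elements), nrow(mesh$nodes), proc.time()[3] - t0)
  sets <- extract_node_sets(mesh, config)
  materials <- list(plate = config$layer_stack$plate_material,
                    trabecular = config$layer_stack$trabecular_material)
  sys <- assemble_system(mesh, materials)
  sys <- apply_boundary_conditions(sys, sets, constraint = constraint)
  disp <- solve_system(sys, tol = config$solver_tolerance,
                       direct_limit = direct_limit)
  say("[%s] solved by %s%s, relres %.2g (%.1fs)", config$label, disp$method,
      if (is.na(disp$iterations)) "" else sprintf(" in %d it", disp$iterations),
      disp$relative_residual, proc.time()[3] - t0)
  stress <- recover_stress(disp, mesh, materials)
  peak <- peak_in_layer(stress, mesh, "plate")
  yield <- config$layer_stack$plate_material$yield_stress
  n_holes <- if (is.null(config$hole_pattern)) 0L else
    nrow(generate_hole_centers(config$hole_pattern, config$layer_stack))
  report <- data.frame(
    label = config$label,
    spacing = if (is.null(config$hole_pattern)) NA_real_
              else config$hole_pattern$spacing,
    n_holes = n_holes,
    n_elements = nrow(mesh$elements),
    n_nodes = nrow(mesh$nodes),
    peak_vm_plate = peak$value,
    robust_peak_vm_plate = peak$robust_value,
    peak_x = peak$coordinates[1], peak_y = peak$coordinates[2],
    peak_z = peak$coordinates[3],
    peak_displacement = max(sqrt(rowSums(disp$u^2))),
    safety_factor = if (is.null(yield)) NA_real_
                    else safety_factor(peak$value, yield),
    yield_stress_used = if (is.null(yield)) NA_real_ else yield,
    stringsAsFactors = FALSE)
  structure(list(config = config, mesh = mesh, node_sets = sets,
                 displacement = disp, stress = stress, report = report,
                 elapsed_s = unname(proc.time()[3] - t0)),
            class = "fe_result")
}

#' @export
print.fe_result <- function(x, ...) {
  r <- x$report
  cat(sprintf("<fe_result> '%s': peak plate von Mises %.3g MPa, SF %.2f, |u|max %.3g mm\n",
              r$label, r$peak_vm_plate,
              r$safety_factor, r$peak_displacement))
  invisible(x)
}

#' @export
summary.fe_result <- function(object, ...) {
  r <- object$report
  cat(sprintf("Configuration '%s'\n", r$label))
  cat(sprintf("  mesh: %d hexahedra (%d plate), %d nodes\n",
              r$n_elements, sum(object$mesh$element_layer == "plate"),
              r$n_nodes))
  if (!is.na(r$spacing))
    cat(sprintf("  holes: %d at %g mm spacing\n", r$n_holes, r$spacing))
  cat(sprintf("  solver: %s, relative residual %.2g\n",
              object$displacement$method,
              object$displacement$relative_residual))
  cat(sprintf("  peak plate von Mises: %.4g MPa at (%.2f, %.2f, %.2f) mm\n",
              r$peak_vm_plate, r$peak_x, r$peak_y, r$peak_z))
  cat(sprintf("  robust (99.9%%) plate von Mises: %.4g MPa\n",
              r$robust_peak_vm_plate))
  cat(sprintf("  peak displacement: %.4g mm\n", r$peak_displacement))
  if (!is.na(r$safety_factor))
    cat(sprintf("  safety factor (peak/yield %g MPa): %.2f %s\n",
                r$yield_stress_used, r$safety_factor,
                if (r$safety_factor < 1) "(< 1: safe)" else "(>= 1: at risk)"))
  invisible(object$report)
}

#' Plot a solved configuration
#'
#' Draws the von Mises stress of the top plate element layer as a filled
#' image (plan view of the articular surface), the region where holes
#' pierce the plate left blank.
#'
#' @param x An [fe_solve()] result.
#' @param ... Passed to [graphics::image()].
#' @export
plot.fe_result <- function(x, ...) {
  mesh <- x$mesh
  d <- mesh$grid_dims
  img <- matrix(NA_real_, d[1], d[2])
  top <- mesh$voxel_index[, 3] == 1L
  img[cbind(mesh$voxel_index[top, 1], mesh$voxel_index[top, 2])] <-
    x$stress$von_mises[top]
  graphics::image(
    x = (seq_len(d[1]) - 0.5) * mesh$voxel_size[1],
    y = (seq_len(d[2]) - 0.5) * mesh$voxel_size[2],
    z = img, asp = 1, xlab = "x (mm)", ylab = "y (mm)",
    main = sprintf("%s: top-layer von Mises (MPa)", x$config$label),
    col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}
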