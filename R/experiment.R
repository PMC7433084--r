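# Orchestration of the eight-configuration hole-spacing experiment and the
# mesh-convergence study.

#' Mesh resolution presets
#'
#' `"fast"`: 0.4 mm lateral / 0.15 mm vertical voxels (~86k elements for
#' the default block; minutes on one CPU). `"paper"`: 0.1 mm isotropic
#' (~2M elements; hours — intended for workstation runs, not for routine
#' checks).
#'
#' @param preset `"fast"` or `"paper"`.
#' @return List with `voxel_size_lateral` and `voxel_size_vertical` (mm).
#' @export
resolution_preset <- function(preset = c("fast", "paper")) {
  preset <- match.arg(preset)
  switch(preset,
         fast = list(voxel_size_lateral = 0.4, voxel_size_vertical = 0.15),
         paper = list(voxel_size_lateral = 0.1, voxel_size_vertical = 0.1))
}

assumptions_ledger <- function(config) {
  pat <- config$hole_pattern
  list(
    hole_diameter_mm = if (is.null(pat)) 1 else pat$hole_diameter,
    spacing_convention = if (is.null(pat)) "edge_to_edge"
                         else pat$spacing_convention,
    defect_extent_mm = if (is.null(pat)) c(8, 8)
                       else c(pat$defect_extent_x, pat$defect_extent_y),
    block_extent_mm = c(config$layer_stack$lateral_extent_x,
                        config$layer_stack$lateral_extent_y),
    load_application = config$load_case$application,
    total_force_N = config$load_case$total_force,
    plate_poisson = config$layer_stack$plate_material$poisson_ratio,
    trabecular_poisson = config$layer_stack$trabecular_material$poisson_ratio)
}

caveat_block <- function() {
  paste(
    "Peak stresses are reported under package default assumptions for",
    "quantities the source experiment leaves unstated (hole diameter,",
    "block and defect extents, load footprint, mesh). Results are",
    "therefore comparable to published per-group values only as bounds",
    "and qualitative structure, not as MPa-for-MPa reproductions.")
}

#' Run the eight-configuration hole-spacing experiment
#'
#' Solves the intact block plus the seven hole spacings (1, 1.5, 2, 2.5,
#' 3, 4, 5 mm) under identical geometry, materials, load and mesh
#' resolution, and collects one safety report per configuration.
#'
#' @param config A [model_config()] supplying everything but the spacing
#'   (defaults to the standard block).
#' @param preset Resolution preset name (see [resolution_preset()]),
#'   overriding the voxel sizes in `config`. Use `NULL` to keep the
#'   config's own voxel sizes.
#' @param spacings Hole spacings in mm.
#' @param out_dir Optional directory; when given, CSV/JSON reports and VTK
#'   fields are written there via [write_experiment()].
#' @param verbose Print per-configuration progress.
#' @return An object of class `experiment_result`: `table` (one row per
#'   configuration), `results` (list of [fe_solve()] outputs), `meta`
#'   (preset, assumptions ledger, caveat block, package version).
#' @export
run_paper_experiment <- function(config = model_config(), preset = "fast",
                                 spacings = c(1, 1.5, 2, 2.5, 3, 4, 5),
                                 out_dir = NULL, verbose = interactive()) {
  stopifnot(inherits(config, "model_config"))
  if (!is.null(preset)) {
    res <- resolution_preset(preset)
    config$voxel_size_lateral <- res$voxel_size_lateral
    config$voxel_size_vertical <- res$voxel_size_vertical
  }
  configs <- make_paper_configs(config, spacings = spacings)
  results <- vector("list", length(configs))
  names(results) <- names(configs)
  for (nm in names(configs)) {
    results[[nm]] <- tryCatch(
      suppressWarnings(fe_solve(configs[[nm]], verbose = verbose)),
      error = function(e) stop(sprintf("configuration '%s' failed: %s",
                                       nm, conditionMessage(e)), call. = FALSE))
  }
  tab <- do.call(rbind, lapply(results, `[[`, "report"))
  rownames(tab) <- NULL
  stopifnot(!anyDuplicated(tab$label), nrow(tab) == length(configs))
  out <- structure(list(
    table = tab, results = results,
    meta = list(preset = if (is.null(preset)) "custom" else preset,
                assumptions = assumptions_ledger(configs[[2L]]),
                caveat = caveat_block(),
                package_version = as.character(utils::packageVersion("subchondralFE")))),
    class = "experiment_result")
  if (!is.null(out_dir)) write_experiment(out, out_dir)
  out
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %d configurations (%s preset)\n",
              nrow(x$table), x$meta$preset))
  print(x$table[, c("label", "spacing", "n_holes", "peak_vm_plate",
                    "robust_peak_vm_plate", "peak_displacement",
                    "safety_factor")],
        digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
summary.experiment_result <- function(object, ...) {
  print(object)
  t <- object$table
  cat(sprintf("\nmax plate peak von Mises: %.4g MPa ('%s'); yield %g MPa\n",
              max(t$peak_vm_plate), t$label[which.max(t$peak_vm_plate)],
              t$yield_stress_used[1]))
  cat(sprintf("all safety factors < 1: %s\n",
              if (all(t$safety_factor < 1)) "yes" else "NO"))
  cat("\n", object$meta$caveat, "\n", sep = "")
  invisible(object$table)
}

#' Plot peak stress and safety factor against hole spacing
#'
#' @param x An [run_paper_experiment()] result.
#' @param ... Unused.
#' @export
plot.experiment_result <- function(x, ...) {
  t <- x$table
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  sp <- ifelse(is.na(t$spacing), 0, t$spacing)
  graphics::plot(sp, t$peak_vm_plate, type = "b", pch = 19,
                 xlab = "hole spacing (mm; 0 = intact)",
                 ylab = "peak plate von Mises (MPa)")
  graphics::abline(h = t$yield_stress_used[1], lty = 2)
  graphics::plot(sp, t$safety_factor, type = "b", pch = 19,
                 xlab = "hole spacing (mm; 0 = intact)",
                 ylab = "safety factor (peak / yield)", ylim = c(0, 1))
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

#' Write experiment reports to disk
#'
#' Emits `report.csv` (the per-configuration table; byte-identical across
#' reruns of the same experiment), `report.json` (table plus metadata,
#' assumptions ledger and caveat block, with a timestamp) and one VTK file
#' per configuration with the von Mises field.
#'
#' @param experiment An [run_paper_experiment()] result.
#' @param dir Output directory (created if needed).
#' @param vtk Also write per-configuration VTK meshes (default TRUE).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir, vtk = TRUE) {
  stopifnot(inherits(experiment, "experiment_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(experiment$table, file.path(dir, "report.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(table = experiment$table, meta = experiment$meta,
         timestamp = format(Sys.time(), tz = "UTC")),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  if (vtk) {
    for (nm in names(experiment$results)) {
      r <- experiment$results[[nm]]
      write_vtk(r$mesh, file.path(dir, paste0(nm, ".vtk")),
                cell_data = list(von_mises = r$stress$von_mises),
                point_vectors = r$displacement$u)
    }
  }
  invisible(dir)
}

#' Mesh-convergence study
#'
#' Re-solves one configuration at a ladder of mesh resolutions and tabulates
#' the peak and robust-peak plate von Mises stress with successive relative
#' changes — the discretisation-error check that voxel meshes (with their
#' jagged hole walls) need before peak stresses are taken at face value.
#'
#' @param config A [model_config()].
#' @param resolutions List of `c(lateral, vertical)` voxel sizes in mm,
#'   coarse to fine (at least two).
#' @return Data frame: voxel sizes, element count, `peak_vm_plate`,
#'   `robust_peak_vm_plate`, `peak_displacement` and `rel_change_*`
#'   columns (NA in the first row). Resolutions too coarse for the plate
#'   are skipped with a warning.
#' @export
convergence_study <- function(config = model_config(), resolutions) {
  stopifnot(inherits(config, "model_config"))
  if (!is.list(resolutions) || length(resolutions) < 2L)
    stop("need at least two resolutions")
  rows <- list()
  for (r in resolutions) {
    cfg <- config
    cfg$voxel_size_lateral <- r[1]
    cfg$voxel_size_vertical <- r[2]
    if (cfg$layer_stack$plate_thickness / r[2] < 2) {
      warning(sprintf("skipping %g/%g mm: fewer than 2 elements through the plate",
                      r[1], r[2]))
      next
    }
    fit <- suppressWarnings(fe_solve(cfg))
    rows[[length(rows) + 1L]] <- data.frame(
      voxel_lateral = r[1], voxel_vertical = r[2],
      n_elements = fit$report$n_elements,
      peak_vm_plate = fit$report$peak_vm_plate,
      robust_peak_vm_plate = fit$report$robust_peak_vm_plate,
      peak_displacement = fit$report$peak_displacement)
  }
  if (length(rows) < 2L)
    stop("fewer than two usable resolutions")
  out <- do.call(rbind, rows)
  relch <- function(v) c(NA, abs(diff(v)) / abs(v[-length(v)]))
  out$rel_change_peak <- relch(out$peak_vm_plate)
  out$rel_change_robust <- relch(out$robust_peak_vm_plate)
  out
}
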