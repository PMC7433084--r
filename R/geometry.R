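#' Microfracture hole pattern
#'
#' A regular grid of vertical cylindrical holes drilled from the articular
#' surface into a rectangular defect region centred in the block. The
#' clinically quoted "distance between holes" is ambiguous; both conventions
#' are supported. With `edge_to_edge` (default), the centre-to-centre pitch
#' is `spacing + hole_diameter`, so a 1 mm spacing with 1 mm holes is a
#' valid (touching-free) pattern.
#'
#' @param spacing Distance between holes in mm (> 0).
#' @param hole_diameter Hole diameter in mm (default 1; the awl diameter).
#' @param hole_depth Hole depth from the articular surface in mm (default 4).
#' @param defect_extent_x,defect_extent_y Defect region extents in mm
#'   (default 8 x 8), centred in the block.
#' @param arrangement `"square_grid"` (default) or `"hex_grid"`.
#' @param spacing_convention `"edge_to_edge"` (default) or
#'   `"center_to_center"`.
#' @return An object of class `hole_pattern`.
#' @export
hole_pattern <- function(spacing, hole_diameter = 1, hole_depth = 4,
                         defect_extent_x = 8, defect_extent_y = 8,
                         arrangement = c("square_grid", "hex_grid"),
                         spacing_convention = c("edge_to_edge",
                                                "center_to_center")) {
  arrangement <- match.arg(arrangement)
  spacing_convention <- match.arg(spacing_convention)
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("spacing must be a single positive number (mm)")
  stopifnot(hole_diameter > 0, hole_depth > 0,
            defect_extent_x > 0, defect_extent_y > 0)
  if (spacing_convention == "center_to_center" && spacing <= hole_diameter)
    stop("center_to_center spacing must exceed the hole diameter")
  structure(list(spacing = as.numeric(spacing),
                 hole_diameter = as.numeric(hole_diameter),
                 hole_depth = as.numeric(hole_depth),
                 defect_extent_x = as.numeric(defect_extent_x),
                 defect_extent_y = as.numeric(defect_extent_y),
                 arrangement = arrangement,
                 spacing_convention = spacing_convention),
            class = "hole_pattern")
}

#' @export
print.hole_pattern <- function(x, ...) {
  cat(sprintf(
    "<hole_pattern> %s, %s spacing %g mm, d = %g mm, depth %g mm, defect %g x %g mm\n",
    x$arrangement, x$spacing_convention, x$spacing, x$hole_diameter,
    x$hole_depth, x$defect_extent_x, x$defect_extent_y))
  invisible(x)
}

hole_pitch <- function(pattern) {
  if (pattern$spacing_convention == "edge_to_edge")
    pattern$spacing + pattern$hole_diameter
  else
    pattern$spacing
}

#' Compressive load case
#'
#' The transmitted tibiofemoral load is applied as a statically determinate
#' downward traction on the articular (top) surface; the bottom surface is
#' fixed in all three directions. Three traction footprints are available:
#' uniform over the whole face, uniform over a circular patch, or a
#' Hertzian (elliptic) pressure profile over a circular patch.
#'
#' @param total_force Total compressive force in N (default 147, two-legged
#'   standing).
#' @param application `"uniform_full_face"` (default), `"uniform_patch"` or
#'   `"hertzian_patch"`.
#' @param patch_radius Contact patch radius in mm (used by the patch modes).
#' @return An object of class `load_case`.
#' @export
load_case <- function(total_force = 147,
                      application = c("uniform_full_face", "uniform_patch",
                                      "hertzian_patch"),
                      patch_radius = NULL) {
  application <- match.arg(application)
  if (!is.numeric(total_force) || length(total_force) != 1L ||
      total_force <= 0)
    stop("total_force must be a single positive number (N)")
  if (application != "uniform_full_face") {
    if (is.null(patch_radius) || !is.numeric(patch_radius) ||
        patch_radius <= 0)
      stop("patch modes require a positive patch_radius (mm)")
  }
  structure(list(total_force = as.numeric(total_force),
                 application = application,
                 patch_radius = if (is.null(patch_radius)) NULL
                                else as.numeric(patch_radius)),
            class = "load_case")
}

#' Full model configuration
#'
#' One simulated configuration: layered geometry, optional hole pattern,
#' load case and mesh resolution. Coordinates: x and y lateral, z downward
#' from the articular surface, origin at a block corner (mm).
#'
#' @param layer_stack A [layer_stack()].
#' @param hole_pattern A [hole_pattern()] or `NULL` for the intact block.
#' @param load_case A [load_case()].
#' @param voxel_size_lateral,voxel_size_vertical Nominal voxel (element)
#'   sizes in mm. The grid dimension along each axis is `ceiling(extent /
#'   voxel_size)` and the realised voxel size is `extent / dims`, so the
#'   grid always covers the block exactly.
#' @param solver_tolerance Relative-residual tolerance for the linear solve
#'   (default 1e-8).
#' @param label Configuration label used in reports.
#' @return An object of class `model_config`.
#' @details At least two elements must fit through the plate thickness
#'   (hard error otherwise). With holes present, fewer than four lateral
#'   elements per hole diameter triggers a warning (the hole cross-section
#'   is then poorly resolved), and fewer than two is an error.
#' @export
model_config <- function(layer_stack = subchondralFE::layer_stack(),
                         hole_pattern = NULL,
                         load_case = subchondralFE::load_case(),
                         voxel_size_lateral = 0.4,
                         voxel_size_vertical = 0.15,
                         solver_tolerance = 1e-8,
                         label = "model") {
  stopifnot(inherits(layer_stack, "layer_stack"),
            inherits(load_case, "load_case"))
  if (!is.null(hole_pattern)) stopifnot(inherits(hole_pattern, "hole_pattern"))
  stopifnot(voxel_size_lateral > 0, voxel_size_vertical > 0,
            solver_tolerance > 0)
  if (layer_stack$plate_thickness / voxel_size_vertical < 2)
    stop("voxel_size_vertical too coarse: need >= 2 elements through the plate")
  if (!is.null(hole_pattern)) {
    if (hole_pattern$hole_depth > total_height(layer_stack))
      stop("hole_depth exceeds the total stack height")
    if (hole_pattern$defect_extent_x + hole_pattern$hole_diameter >
          layer_stack$lateral_extent_x ||
        hole_pattern$defect_extent_y + hole_pattern$hole_diameter >
          layer_stack$lateral_extent_y)
      stop("defect region (plus hole overhang) does not fit inside the lateral extents")
    ratio <- hole_pattern$hole_diameter / voxel_size_lateral
    if (ratio < 2)
      stop("voxel_size_lateral too coarse: fewer than 2 elements per hole diameter")
    if (ratio < 4)
      warning(sprintf(
        "only %.1f lateral elements per hole diameter; hole walls are coarsely resolved",
        ratio))
  }
  structure(list(layer_stack = layer_stack,
                 hole_pattern = hole_pattern,
                 load_case = load_case,
                 voxel_size_lateral = as.numeric(voxel_size_lateral),
                 voxel_size_vertical = as.numeric(voxel_size_vertical),
                 solver_tolerance = as.numeric(solver_tolerance),
                 label = as.character(label)),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("<model_config> '%s': %g x %g x %g mm, voxels %g/%g mm, %s\n",
              x$label, x$layer_stack$lateral_extent_x,
              x$layer_stack$lateral_extent_y, total_height(x$layer_stack),
              x$voxel_size_lateral, x$voxel_size_vertical,
              if (is.null(x$hole_pattern)) "intact"
              else sprintf("holes at %g mm spacing", x$hole_pattern$spacing)))
  invisible(x)
}

#' Hole centre coordinates for a pattern
#'
#' Lays out hole centres on the chosen grid over the defect region (centred
#' in the block): the maximal centred grid whose hole centres lie within the
#' defect rectangle. Hole walls may overhang the defect boundary by up to one
#' radius but always stay well inside the block (enforced at construction).
#'
#' @param pattern A [hole_pattern()].
#' @param stack A [layer_stack()] giving the block extents.
#' @return A two-column matrix of (x, y) centres in mm. Signals an error of
#'   class `empty_hole_pattern` when not even one hole fits.
#' @export
generate_hole_centers <- function(pattern, stack) {
  stopifnot(inherits(pattern, "hole_pattern"), inherits(stack, "layer_stack"))
  pitch <- hole_pitch(pattern)
  r <- pattern$hole_diameter / 2
  cx <- stack$lateral_extent_x / 2
  cy <- stack$lateral_extent_y / 2
  hx <- pattern$defect_extent_x / 2
  hy <- pattern$defect_extent_y / 2
  if (hx + r > stack$lateral_extent_x / 2 ||
      hy + r > stack$lateral_extent_y / 2)
    stop("hole pattern does not fit inside the block")
  if (pattern$defect_extent_x < pattern$hole_diameter ||
      pattern$defect_extent_y < pattern$hole_diameter)
    stop(structure(class = c("empty_hole_pattern", "error", "condition"),
                   list(message = "defect region too small for one hole",
                        call = sys.call(-1))))
  # maximal centred 1-D grid with points in [-half, half]
  grid_coords <- function(half_extent, step) {
    n <- floor(2 * half_extent / step + 1e-9) + 1
    step * (seq_len(n) - (n + 1) / 2)
  }
  if (pattern$arrangement == "square_grid") {
    xs <- grid_coords(hx, pitch)
    ys <- grid_coords(hy, pitch)
    centers <- cbind(x = rep(xs, times = length(ys)),
                     y = rep(ys, each = length(xs)))
  } else {
    # hex grid: rows pitch*sqrt(3)/2 apart, alternate rows offset pitch/2
    rowstep <- pitch * sqrt(3) / 2
    ys <- grid_coords(hy, rowstep)
    centers <- do.call(rbind, lapply(seq_along(ys), function(iy) {
      off <- if (iy %% 2 == 0) pitch / 2 else 0
      xs <- off + pitch * seq(-ceiling(hx / pitch) - 1, ceiling(hx / pitch) + 1)
      xs <- xs[abs(xs) <= hx + 1e-9]
      if (!length(xs)) return(NULL)
      cbind(x = xs, y = rep(ys[iy], length(xs)))
    }))
  }
  if (is.null(centers) || nrow(centers) == 0L)
    stop(structure(class = c("empty_hole_pattern", "error", "condition"),
                   list(message = "defect region too small for one hole",
                        call = sys.call(-1))))
  centers[, 1] <- centers[, 1] + cx
  centers[, 2] <- centers[, 2] + cy
  centers[order(centers[, 2], centers[, 1]), , drop = FALSE]
}

#' Region membership of a point
#'
#' Classifies points of the block as subchondral plate, trabecular bone,
#' hole void, or outside the block. Holes are vertical cylinders from the
#' top surface down to `hole_depth`; since the default depth (4 mm) exceeds
#' the plate thickness (0.3 mm), every hole perforates the plate and enters
#' the trabecular layer.
#'
#' @param points An n x 3 matrix (or length-3 vector) of (x, y, z)
#'   coordinates in mm, z downward from the top surface.
#' @param config A [model_config()].
#' @return A character vector with values `"plate"`, `"trabecular"`,
#'   `"hole_void"`, `"outside"`.
#' @export
geometry_membership <- function(points, config) {
  stopifnot(inherits(config, "model_config"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  stopifnot(ncol(points) == 3)
  st <- config$layer_stack
  H <- total_height(st)
  x <- points[, 1]; y <- points[, 2]; z <- points[, 3]
  out <- x < 0 | x > st$lateral_extent_x | y < 0 | y > st$lateral_extent_y |
    z < 0 | z > H
  res <- ifelse(z <= st$plate_thickness, "plate", "trabecular")
  if (!is.null(config$hole_pattern)) {
    pat <- config$hole_pattern
    centers <- generate_hole_centers(pat, st)
    r2 <- (pat$hole_diameter / 2)^2
    in_hole <- rep(FALSE, nrow(points))
    candidate <- z <= pat$hole_depth & !out
    if (any(candidate)) {
      idx <- which(candidate)
      for (h in seq_len(nrow(centers))) {
        d2 <- (x[idx] - centers[h, 1])^2 + (y[idx] - centers[h, 2])^2
        in_hole[idx[d2 <= r2]] <- TRUE
      }
    }
    res[in_hole] <- "hole_void"
  }
  res[out] <- "outside"
  res
}

#' The eight study configurations
#'
#' One intact configuration plus hole spacings of 1, 1.5, 2, 2.5, 3, 4 and
#' 5 mm, identical in every other respect (geometry, materials, 4 mm hole
#' depth, 147 N load, mesh resolution).
#'
#' @param defaults A [model_config()] providing everything except the hole
#'   spacing; its `hole_pattern` slot, if any, supplies the hole diameter,
#'   depth, defect extents and conventions.
#' @param spacings Hole spacings in mm (default the seven study values).
#' @return A named list of 8 `model_config` objects (`intact`, `1mm`, ...).
#' @export
make_paper_configs <- function(defaults = model_config(),
                               spacings = c(1, 1.5, 2, 2.5, 3, 4, 5)) {
  stopifnot(inherits(defaults, "model_config"))
  proto <- defaults$hole_pattern
  if (is.null(proto)) proto <- hole_pattern(spacing = 1)
  configs <- vector("list", length(spacings) + 1L)
  intact <- defaults
  intact$hole_pattern <- NULL
  intact$label <- "intact"
  configs[[1L]] <- intact
  for (i in seq_along(spacings)) {
    cfg <- defaults
    pat <- proto
    pat$spacing <- spacings[i]
    cfg$hole_pattern <- pat
    cfg$label <- sprintf("%gmm", spacings[i])
    configs[[i + 1L]] <- cfg
  }
  names(configs) <- vapply(configs, `[[`, "", "label")
  if (anyDuplicated(names(configs))) stop("config labels are not unique")
  configs
}

#' Read / write a model configuration
#'
#' Serialises a [model_config()] to YAML (or JSON, by file extension)
#' mirroring the constructor field names; lengths in mm, forces in N,
#' moduli in MPa.
#'
#' @param config A [model_config()].
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_model_config` returns a `model_config`;
#'   `write_model_config` returns `path` invisibly.
#' @export
write_model_config <- function(config, path) {
  stopifnot(inherits(config, "model_config"))
  x <- list(
    label = config$label,
    layer_stack = list(
      plate_thickness = config$layer_stack$plate_thickness,
      trabecular_thickness = config$layer_stack$trabecular_thickness,
      lateral_extent_x = config$layer_stack$lateral_extent_x,
      lateral_extent_y = config$layer_stack$lateral_extent_y,
      plate_material = unclass(config$layer_stack$plate_material),
      trabecular_material = unclass(config$layer_stack$trabecular_material)),
    hole_pattern = if (is.null(config$hole_pattern)) NULL
                   else unclass(config$hole_pattern),
    load_case = unclass(config$load_case),
    voxel_size_lateral = config$voxel_size_lateral,
    voxel_size_vertical = config$voxel_size_vertical,
    solver_tolerance = config$solver_tolerance)
  x <- rapply(x, function(v) v, how = "replace") # drop attributes
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  mat <- function(m) material_spec(m$name, m$young_modulus, m$poisson_ratio,
                                   m$yield_stress)
  st <- layer_stack(
    plate_thickness = x$layer_stack$plate_thickness,
    trabecular_thickness = x$layer_stack$trabecular_thickness,
    lateral_extent_x = x$layer_stack$lateral_extent_x,
    lateral_extent_y = x$layer_stack$lateral_extent_y,
    plate_material = mat(x$layer_stack$plate_material),
    trabecular_material = mat(x$layer_stack$trabecular_material))
  hp <- if (is.null(x$hole_pattern)) NULL else
    hole_pattern(spacing = x$hole_pattern$spacing,
                 hole_diameter = x$hole_pattern$hole_diameter,
                 hole_depth = x$hole_pattern$hole_depth,
                 defect_extent_x = x$hole_pattern$defect_extent_x,
                 defect_extent_y = x$hole_pattern$defect_extent_y,
                 arrangement = x$hole_pattern$arrangement,
                 spacing_convention = x$hole_pattern$spacing_convention)
  lc <- load_case(total_force = x$load_case$total_force,
                  application = x$load_case$application,
                  patch_radius = x$load_case$patch_radius)
  model_config(layer_stack = st, hole_pattern = hp, load_case = lc,
               voxel_size_lateral = x$voxel_size_lateral,
               voxel_size_vertical = x$voxel_size_vertical,
               solver_tolerance = x$solver_tolerance,
               label = x$label)
}
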