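#' Isotropic linear-elastic material for one bone layer
#'
#' Bundles the elastic constants (and optionally a yield stress) of one
#' homogenised bone layer. All stresses and moduli are in MPa at the user
#' interface; the solver works in N and mm throughout, so N/mm^2 == MPa
#' falls out without unit conversion.
#'
#' @param name Label used in reports.
#' @param young_modulus Young's modulus in MPa (> 0).
#' @param poisson_ratio Poisson's ratio, in [0, 0.5).
#' @param yield_stress Optional yield stress in MPa (> 0); required only for
#'   layers that enter a safety-factor computation.
#' @return An object of class `material_spec`.
#' @examples
#' material_spec("plate", young_modulus = 17000, poisson_ratio = 0.3,
#'               yield_stress = 135)
#' @export
material_spec <- function(name, young_modulus, poisson_ratio,
                          yield_stress = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(young_modulus) || length(young_modulus) != 1L ||
      young_modulus <= 0)
    stop("young_modulus must be a single positive number (MPa)")
  if (!is.numeric(poisson_ratio) || length(poisson_ratio) != 1L ||
      poisson_ratio < 0 || poisson_ratio >= 0.5)
    stop("poisson_ratio must lie in [0, 0.5)")
  if (!is.null(yield_stress)) {
    if (!is.numeric(yield_stress) || length(yield_stress) != 1L ||
        yield_stress <= 0)
      stop("yield_stress must be a single positive number (MPa)")
  }
  structure(list(name = name,
                 young_modulus = as.numeric(young_modulus),
                 poisson_ratio = as.numeric(poisson_ratio),
                 yield_stress = if (is.null(yield_stress)) NULL
                                else as.numeric(yield_stress)),
            class = "material_spec")
}

#' @export
print.material_spec <- function(x, ...) {
  cat(sprintf("<material_spec> %s: E = %g MPa, nu = %g", x$name,
              x$young_modulus, x$poisson_ratio))
  if (!is.null(x$yield_stress))
    cat(sprintf(", yield = %g MPa", x$yield_stress))
  cat("\n")
  invisible(x)
}

#' Default subchondral bone plate material
#'
#' E = 17 GPa, nu = 0.3, yield stress 135 MPa. Dense cortical-like bone of
#' the thin plate directly under the articular cartilage.
#'
#' @return A [material_spec()].
#' @export
subchondral_plate_material <- function() {
  material_spec("subchondral_plate", young_modulus = 17000,
                poisson_ratio = 0.3, yield_stress = 135)
}

#' Default homogenised trabecular bone material
#'
#' E = 700 MPa. The Poisson's ratio defaults to 0.3; a value of 0.25 also
#' appears in the literature for this tissue and can be passed instead.
#'
#' @param poisson_ratio Poisson's ratio (default 0.3).
#' @return A [material_spec()].
#' @export
trabecular_bone_material <- function(poisson_ratio = 0.3) {
  material_spec("trabecular", young_modulus = 700,
                poisson_ratio = poisson_ratio)
}

#' Two-layer osteochondral stack
#'
#' Describes the laterally-uniform layering of the block: a thin dense
#' subchondral plate on top of a thick homogenised trabecular layer.
#' z is measured downward from the articular (top) surface, origin at a
#' block corner; the plate occupies 0 <= z < plate_thickness.
#'
#' @param plate_thickness Plate thickness in mm (default 0.3).
#' @param trabecular_thickness Trabecular layer thickness in mm (default 7.7).
#' @param lateral_extent_x,lateral_extent_y Block extents in mm (default 16).
#' @param plate_material,trabecular_material [material_spec()] objects.
#' @return An object of class `layer_stack`.
#' @export
layer_stack <- function(plate_thickness = 0.3, trabecular_thickness = 7.7,
                        lateral_extent_x = 16, lateral_extent_y = 16,
                        plate_material = subchondral_plate_material(),
                        trabecular_material = trabecular_bone_material()) {
  dims <- c(plate_thickness, trabecular_thickness,
            lateral_extent_x, lateral_extent_y)
  if (!is.numeric(dims) || any(dims <= 0))
    stop("all thicknesses and extents must be positive")
  stopifnot(inherits(plate_material, "material_spec"),
            inherits(trabecular_material, "material_spec"))
  structure(list(plate_thickness = as.numeric(plate_thickness),
                 trabecular_thickness = as.numeric(trabecular_thickness),
                 lateral_extent_x = as.numeric(lateral_extent_x),
                 lateral_extent_y = as.numeric(lateral_extent_y),
                 plate_material = plate_material,
                 trabecular_material = trabecular_material),
            class = "layer_stack")
}

total_height <- function(stack) {
  stack$plate_thickness + stack$trabecular_thickness
}

#' @export
print.layer_stack <- function(x, ...) {
  cat(sprintf(
    "<layer_stack> %g x %g mm block, plate %g mm / trabecular %g mm\n",
    x$lateral_extent_x, x$lateral_extent_y,
    x$plate_thickness, x$trabecular_thickness))
  invisible(x)
}
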