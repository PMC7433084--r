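#' Recover element centroid stresses
#'
#' Strain at each element centroid from the trilinear shape-function
#' gradients, then Cauchy stress by isotropic Hooke's law with that
#' element's layer material. No nodal averaging or extrapolation is done:
#' centroid values are deterministic and keep voxel-rim artefacts local.
#'
#' @param displacements A [solve_system()] result.
#' @param mesh The [build_hex_mesh()] mesh the solution lives on.
#' @param materials Named list of [material_spec()] per layer label.
#' @return An object of class `stress_field`: `stress` (m x 6 matrix, MPa,
#'   Voigt order sxx, syy, szz, sxy, syz, szx) and `von_mises` (length m).
#' @export
recover_stress <- function(displacements, mesh,
                           materials = list(
                             plate = subchondral_plate_material(),
                             trabecular = trabecular_bone_material())) {
  stopifnot(inherits(displacements, "displacement_field"),
            inherits(mesh, "hex_mesh"))
  lay <- unique(mesh$element_layer)
  if (!all(lay %in% names(materials)))
    stop("layer/material mismatch: ", paste(setdiff(lay, names(materials)),
                                            collapse = ", "))
  nel <- nrow(mesh$elements)
  # element displacement vectors: m x 24
  ux <- displacements$u[, 1]; uy <- displacements$u[, 2]
  uz <- displacements$u[, 3]
  Ue <- matrix(0, nel, 24)
  for (n in 1:8) {
    Ue[, 3 * (n - 1) + 1] <- ux[mesh$elements[, n]]
    Ue[, 3 * (n - 1) + 2] <- uy[mesh$elements[, n]]
    Ue[, 3 * n] <- uz[mesh$elements[, n]]
  }
  # congruent boxes: one centroid B per mesh
  X1 <- mesh$nodes[mesh$elements[1, ], ]
  dN <- hex_dshape(0, 0, 0)
  J <- dN %*% X1
  B0 <- hex_B(solve(J, dN))          # 6 x 24
  eps <- Ue %*% t(B0)                # m x 6 (engineering shears)
  stress <- matrix(0, nel, 6)
  for (l in lay) {
    sel <- mesh$element_layer == l
    stress[sel, ] <- eps[sel, , drop = FALSE] %*% t(elastic_D(materials[[l]]))
  }
  colnames(stress) <- c("sxx", "syy", "szz", "sxy", "syz", "szx")
  structure(list(stress = stress, von_mises = von_mises(stress)),
            class = "stress_field")
}

#' @export
print.stress_field <- function(x, ...) {
  cat(sprintf("<stress_field> %d elements, von Mises max %.4g MPa\n",
              nrow(x$stress), max(x$von_mises)))
  invisible(x)
}

#' Von Mises equivalent stress
#'
#' \deqn{\sigma_{vm} = \sqrt{\tfrac12[(\sigma_{xx}-\sigma_{yy})^2 +
#'   (\sigma_{yy}-\sigma_{zz})^2 + (\sigma_{zz}-\sigma_{xx})^2] +
#'   3(\sigma_{xy}^2+\sigma_{yz}^2+\sigma_{zx}^2)}}
#'
#' Invariant under coordinate rotation.
#'
#' @param stress_tensor Length-6 vector or m x 6 matrix in Voigt order
#'   (sxx, syy, szz, sxy, syz, szx), MPa.
#' @return Scalar or length-m vector of equivalent stresses (MPa).
#' @examples
#' von_mises(c(10, 0, 0, 0, 0, 0))   # uniaxial: 10
#' von_mises(c(5, 5, 5, 0, 0, 0))    # hydrostatic: 0
#' von_mises(c(0, 0, 0, 10, 0, 0))   # pure shear: 10 * sqrt(3)
#' @export
von_mises <- function(stress_tensor) {
  s <- if (is.null(dim(stress_tensor))) matrix(stress_tensor, ncol = 6)
       else as.matrix(stress_tensor)
  stopifnot(ncol(s) == 6)
  v <- sqrt(0.5 * ((s[, 1] - s[, 2])^2 + (s[, 2] - s[, 3])^2 +
                     (s[, 3] - s[, 1])^2) +
              3 * (s[, 4]^2 + s[, 5]^2 + s[, 6]^2))
  if (is.null(dim(stress_tensor))) as.numeric(v) else v
}

#' Peak von Mises stress within a layer
#'
#' Maximum element-centroid von Mises stress over the elements of one
#' layer, with ties broken by the lowest element index, plus a robust
#' 99.9th-percentile companion value (voxel-jagged hole rims create
#' isolated artificial stress spikes; the raw maximum remains the headline
#' number).
#'
#' @param field A [recover_stress()] result.
#' @param mesh The corresponding mesh.
#' @param layer `"plate"` or `"trabecular"`.
#' @return List: `value` (MPa), `element` (index into the mesh),
#'   `coordinates` (element centroid, mm), `robust_value` (99.9th
#'   percentile, MPa).
#' @export
peak_in_layer <- function(field, mesh, layer = "plate") {
  stopifnot(inherits(field, "stress_field"), inherits(mesh, "hex_mesh"))
  sel <- which(mesh$element_layer == layer)
  if (!length(sel)) stop("layer '", layer, "' not present in mesh")
  vm <- field$von_mises[sel]
  i <- which.max(vm)  # which.max takes the first maximum: lowest index
  el <- sel[i]
  centroid <- colMeans(mesh$nodes[mesh$elements[el, ], ])
  list(value = vm[i], element = el, coordinates = centroid,
       robust_value = as.numeric(stats::quantile(vm, 0.999, names = FALSE)))
}

#' Safety factor against plate yield
#'
#' Ratio of peak von Mises stress to the yield stress. In this study's
#' convention values below 1 indicate a safe configuration (the inverse of
#' the usual engineering safety factor). Reported values are conventionally
#' rounded to two decimals.
#'
#' @param peak_stress Peak von Mises stress, MPa.
#' @param yield_stress Yield stress, MPa (> 0); 135 MPa for the subchondral
#'   plate.
#' @return `peak_stress / yield_stress` (unrounded).
#' @examples
#' round(safety_factor(52.8, 135), 2)  # 0.39
#' @export
safety_factor <- function(peak_stress, yield_stress = 135) {
  if (!is.numeric(yield_stress) || any(yield_stress <= 0))
    stop("yield_stress must be positive")
  peak_stress / yield_stress
}
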