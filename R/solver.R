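# Small-strain isotropic linear elasticity on trilinear hexahedra.
# DOF ordering: node n owns dofs 3(n-1)+1..3n for (ux, uy, uz); nodes are
# numbered lexicographically by the mesh builder, so runs are reproducible.

# isotropic elasticity matrix (Voigt order xx, yy, zz, xy, yz, zx;
# engineering shear strains)
elastic_D <- function(material) {
  E <- material$young_modulus
  nu <- material$poisson_ratio
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}

# natural coordinates of the 8 nodes (matches the mesh node ordering)
HEX_XI <- c(-1, 1, 1, -1, -1, 1, 1, -1)
HEX_ETA <- c(-1, -1, 1, 1, -1, -1, 1, 1)
HEX_ZETA <- c(-1, -1, -1, -1, 1, 1, 1, 1)

# shape-function gradients wrt natural coords at (xi, eta, zeta): 3 x 8
hex_dshape <- function(xi, eta, zeta) {
  rbind(0.125 * HEX_XI * (1 + eta * HEX_ETA) * (1 + zeta * HEX_ZETA),
        0.125 * (1 + xi * HEX_XI) * HEX_ETA * (1 + zeta * HEX_ZETA),
        0.125 * (1 + xi * HEX_XI) * (1 + eta * HEX_ETA) * HEX_ZETA)
}

# strain-displacement matrix from physical shape gradients (3 x 8) -> 6 x 24
hex_B <- function(dNx) {
  B <- matrix(0, 6, 24)
  ix <- 3 * (0:7) + 1
  B[1, ix] <- dNx[1, ]
  B[2, ix + 1] <- dNx[2, ]
  B[3, ix + 2] <- dNx[3, ]
  B[4, ix] <- dNx[2, ]; B[4, ix + 1] <- dNx[1, ]
  B[5, ix + 1] <- dNx[3, ]; B[5, ix + 2] <- dNx[2, ]
  B[6, ix] <- dNx[3, ]; B[6, ix + 2] <- dNx[1, ]
  B
}

#' Element stiffness matrix of a trilinear hexahedron
#'
#' Standard isoparametric 8-node hexahedron with full 2 x 2 x 2 Gauss
#' quadrature. The returned 24 x 24 matrix is symmetric with exactly six
#' rigid-body null modes for any valid (non-inverted) element.
#'
#' @param corner_coordinates 8 x 3 matrix of node positions (mm), in the
#'   mesh node ordering (bottom face counter-clockwise, then top face).
#' @param material A [material_spec()].
#' @return 24 x 24 numeric stiffness matrix (N/mm).
#' @export
element_stiffness <- function(corner_coordinates, material) {
  X <- as.matrix(corner_coordinates)
  stopifnot(nrow(X) == 8L, ncol(X) == 3L, inherits(material, "material_spec"))
  D <- elastic_D(material)
  g <- 1 / sqrt(3)
  Ke <- matrix(0, 24, 24)
  for (a in c(-g, g)) for (b in c(-g, g)) for (c in c(-g, g)) {
    dN <- hex_dshape(a, b, c)
    J <- dN %*% X                       # 3 x 3 Jacobian
    detJ <- det(J)
    if (detJ <= 0)
      stop(sprintf("inverted element: Jacobian determinant %g at a quadrature point",
                   detJ))
    dNx <- solve(J, dN)
    B <- hex_B(dNx)
    Ke <- Ke + crossprod(B, D %*% B) * detJ
  }
  (Ke + t(Ke)) / 2
}

element_dofs <- function(conn) {
  # conn: m x 8 node indices -> m x 24 dof indices
  edof <- matrix(0L, nrow(conn), 24L)
  for (n in 1:8) {
    edof[, 3L * (n - 1L) + 1L] <- 3L * (conn[, n] - 1L) + 1L
    edof[, 3L * (n - 1L) + 2L] <- 3L * (conn[, n] - 1L) + 2L
    edof[, 3L * n] <- 3L * conn[, n]
  }
  edof
}

#' Assemble the global sparse stiffness system
#'
#' Connectivity-mapped sum of element stiffness matrices into a symmetric
#' sparse matrix. Voxel meshes contain only two distinct element geometries'
#' worth of stiffness (one per material layer, all elements being congruent
#' boxes), which the assembly exploits; a general per-element path covers
#' meshes whose elements differ.
#'
#' @param mesh A [build_hex_mesh()] result.
#' @param materials Named list with entries `plate` and `trabecular`, each a
#'   [material_spec()] (defaults from the standard two-layer model).
#' @return An object of class `fe_system`: `K` (dsCMatrix, N/mm), `load`
#'   (numeric, N), `constrained_dofs` (integer, empty until
#'   [apply_boundary_conditions()]), `n_dofs`, `mesh`.
#' @export
assemble_system <- function(mesh,
                            materials = list(
                              plate = subchondral_plate_material(),
                              trabecular = trabecular_bone_material())) {
  stopifnot(inherits(mesh, "hex_mesh"))
  lay <- unique(mesh$element_layer)
  if (!all(lay %in% names(materials)))
    stop("unknown layer label: ", paste(setdiff(lay, names(materials)),
                                        collapse = ", "))
  nel <- nrow(mesh$elements)
  ndof <- 3L * nrow(mesh$nodes)
  edof <- element_dofs(mesh$elements)
  # one stiffness per layer: all voxel elements are congruent boxes
  ke_flat <- matrix(0, length(lay), 576)
  rownames(ke_flat) <- lay
  for (l in lay) {
    e1 <- which(mesh$element_layer == l)[1]
    Ke <- element_stiffness(mesh$nodes[mesh$elements[e1, ], ], materials[[l]])
    ke_flat[l, ] <- as.vector(Ke)
  }
  ii <- edof[, rep(1:24, times = 24), drop = FALSE]
  jj <- edof[, rep(1:24, each = 24), drop = FALSE]
  xx <- ke_flat[mesh$element_layer, , drop = FALSE]
  keep <- ii >= jj   # lower triangle only; Matrix stores symmetric
  K <- Matrix::sparseMatrix(i = ii[keep], j = jj[keep], x = xx[keep],
                            dims = c(ndof, ndof), symmetric = TRUE)
  structure(list(K = K, load = numeric(ndof),
                 constrained_dofs = integer(0), n_dofs = ndof, mesh = mesh),
            class = "fe_system")
}

#' @export
print.fe_system <- function(x, ...) {
  cat(sprintf("<fe_system> %d dofs, %d constrained, nnz(K) = %d\n",
              x$n_dofs, length(x$constrained_dofs),
              length(x$K@x)))
  invisible(x)
}

#' Apply boundary conditions
#'
#' Marks the fixed degrees of freedom and fills the nodal load vector.
#' The study constraint (`"fixed"`) clamps all three displacement
#' components of every bottom-surface node. The `"roller_z"` variant
#' (a verification fixture, not part of the study model) constrains only
#' the vertical component at the bottom plus a minimal 3-2-1 set of lateral
#' pins to remove the in-plane rigid modes.
#'
#' @param system An [assemble_system()] result.
#' @param sets An [extract_node_sets()] result.
#' @param constraint `"fixed"` (default) or `"roller_z"`.
#' @return The `fe_system` with `constrained_dofs` and `load` filled. Loads
#'   act downward (+z in the z-down convention).
#' @export
apply_boundary_conditions <- function(system, sets,
                                      constraint = c("fixed", "roller_z")) {
  constraint <- match.arg(constraint)
  stopifnot(inherits(system, "fe_system"), inherits(sets, "node_sets"))
  if (!length(sets$bottom_surface))
    stop("empty bottom surface: system would be singular")
  bn <- sets$bottom_surface
  if (constraint == "fixed") {
    cdof <- c(3L * (bn - 1L) + 1L, 3L * (bn - 1L) + 2L, 3L * bn)
  } else {
    cdof <- 3L * bn
    nodes <- system$mesh$nodes
    # pin node nearest the origin corner of the bottom face in x and y,
    # and a second bottom node farthest in x in y only (kills z-rotation)
    d0 <- nodes[bn, 1]^2 + nodes[bn, 2]^2
    a <- bn[which.min(d0)]
    b <- bn[which.max(nodes[bn, 1])]
    cdof <- c(cdof, 3L * (a - 1L) + 1L, 3L * (a - 1L) + 2L, 3L * (b - 1L) + 2L)
  }
  f <- numeric(system$n_dofs)
  f[3L * sets$loaded_nodes] <- sets$force_shares  # +z is downward
  system$constrained_dofs <- sort(unique(cdof))
  system$load <- f
  system
}

# diagonally preconditioned conjugate gradients for SPD sparse K
jacobi_pcg <- function(K, b, tol, maxit) {
  M <- Matrix::diag(K)
  if (any(M <= 0)) stop("non-positive diagonal: system is not SPD")
  x <- numeric(length(b))
  r <- b
  z <- r / M
  p <- z
  rz <- sum(r * z)
  nb <- sqrt(sum(b * b))
  if (nb == 0) return(list(x = x, iterations = 0L, relative_residual = 0,
                           history = numeric(0)))
  hist <- numeric(0)
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(K %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rel <- sqrt(sum(r * r)) / nb
    hist[it] <- rel
    if (rel < tol)
      return(list(x = x, iterations = it, relative_residual = rel,
                  history = hist))
    z <- r / M
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  stop(structure(class = c("pcg_no_convergence", "error", "condition"),
                 list(message = sprintf(
                   "PCG did not reach tol %g in %d iterations (final residual %g)",
                   tol, maxit, rel),
                   call = NULL, history = hist)))
}

#' Solve the constrained linear system
#'
#' Eliminates the constrained degrees of freedom and solves the reduced
#' symmetric positive-definite system: by sparse Cholesky factorisation
#' below `direct_limit` free DOFs, by diagonally preconditioned conjugate
#' gradients above it (the default limit keeps the direct route for small
#' verification meshes; production voxel meshes go through PCG). Verifies
#' the relative residual and the global reaction balance before returning.
#'
#' @param system An [apply_boundary_conditions()] result.
#' @param tol Relative-residual tolerance (default 1e-8).
#' @param direct_limit Free-DOF count below which the direct solver is used.
#' @param maxit PCG iteration budget.
#' @return An object of class `displacement_field`: `u` (n_nodes x 3 matrix,
#'   mm), plus solver statistics (`method`, `iterations`,
#'   `relative_residual`, `reaction_force` in N).
#' @export
solve_system <- function(system, tol = 1e-8, direct_limit = 15000,
                         maxit = 20000) {
  stopifnot(inherits(system, "fe_system"))
  if (!length(system$constrained_dofs))
    stop("no constraints applied: system is singular")
  free <- setdiff(seq_len(system$n_dofs), system$constrained_dofs)
  Kf <- system$K[free, free]
  ff <- system$load[free]
  if (length(free) <= direct_limit) {
    ch <- Matrix::Cholesky(Kf, LDL = FALSE)
    uf <- as.numeric(Matrix::solve(ch, ff))
    method <- "sparse_cholesky"
    iterations <- NA_integer_
  } else {
    res <- jacobi_pcg(Kf, ff, tol = tol, maxit = maxit)
    uf <- res$x
    method <- "jacobi_pcg"
    iterations <- res$iterations
  }
  rel <- sqrt(sum((as.numeric(Kf %*% uf) - ff)^2)) / max(sqrt(sum(ff^2)),
                                                         .Machine$double.xmin)
  if (sum(ff^2) > 0 && rel > max(tol, 1e-7) * 10)
    stop(sprintf("solver residual %g exceeds tolerance", rel))
  u <- numeric(system$n_dofs)
  u[free] <- uf
  # reactions at constrained dofs; total must balance the applied load
  r_all <- as.numeric(system$K %*% u) - system$load
  cz <- system$constrained_dofs
  reaction <- c(sum(r_all[cz[cz %% 3L == 1L]]),
                sum(r_all[cz[cz %% 3L == 2L]]),
                sum(r_all[cz[cz %% 3L == 0L]]))
  applied <- c(sum(system$load[seq(1, system$n_dofs, 3)]),
               sum(system$load[seq(2, system$n_dofs, 3)]),
               sum(system$load[seq(3, system$n_dofs, 3)]))
  if (sqrt(sum(applied^2)) > 0) {
    imbalance <- sqrt(sum((reaction + applied)^2)) / sqrt(sum(applied^2))
    if (imbalance > 1e-6)
      warning(sprintf("reaction/load imbalance %g relative", imbalance))
  }
  structure(list(u = matrix(u, ncol = 3, byrow = TRUE),
                 method = method, iterations = iterations,
                 relative_residual = rel, reaction_force = reaction),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf(
    "<displacement_field> %d nodes, |u|max = %.4g mm (%s%s, relres %.2g)\n",
    nrow(x$u), max(sqrt(rowSums(x$u^2))), x$method,
    if (is.na(x$iterations)) "" else sprintf(", %d it", x$iterations),
    x$relative_residual))
  invisible(x)
}
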