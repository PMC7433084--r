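# Independent dense brute-force elasticity implementation used as the
# oracle for the sparse production path. Kept deliberately separate:
# shape-function gradients come from central finite differences of the
# shape-function values, quadrature is 3x3x3 Gauss-Legendre, assembly and
# solve are dense base-R.

oracle_shape_values <- function(xi, eta, zeta) {
  sx <- c(-1, 1, 1, -1, -1, 1, 1, -1)
  sy <- c(-1, -1, 1, 1, -1, -1, 1, 1)
  sz <- c(-1, -1, -1, -1, 1, 1, 1, 1)
  (1 + xi * sx) * (1 + eta * sy) * (1 + zeta * sz) / 8
}

oracle_dshape_fd <- function(xi, eta, zeta, h = 1e-6) {
  rbind(
    (oracle_shape_values(xi + h, eta, zeta) -
       oracle_shape_values(xi - h, eta, zeta)) / (2 * h),
    (oracle_shape_values(xi, eta + h, zeta) -
       oracle_shape_values(xi, eta - h, zeta)) / (2 * h),
    (oracle_shape_values(xi, eta, zeta + h) -
       oracle_shape_values(xi, eta, zeta - h)) / (2 * h))
}

oracle_D <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}

# 3-point Gauss-Legendre on [-1, 1]
oracle_gauss3 <- list(points = c(-sqrt(3 / 5), 0, sqrt(3 / 5)),
                      weights = c(5 / 9, 8 / 9, 5 / 9))

oracle_element_stiffness <- function(X, E, nu) {
  D <- oracle_D(E, nu)
  Ke <- matrix(0, 24, 24)
  gp <- oracle_gauss3
  for (a in 1:3) for (b in 1:3) for (c in 1:3) {
    dN <- oracle_dshape_fd(gp$points[a], gp$points[b], gp$points[c])
    J <- dN %*% X
    dNx <- solve(J, dN)
    B <- matrix(0, 6, 24)
    for (n in 1:8) {
      i <- 3 * (n - 1) + 1
      B[1, i] <- dNx[1, n]; B[2, i + 1] <- dNx[2, n]; B[3, i + 2] <- dNx[3, n]
      B[4, i] <- dNx[2, n]; B[4, i + 1] <- dNx[1, n]
      B[5, i + 1] <- dNx[3, n]; B[5, i + 2] <- dNx[2, n]
      B[6, i] <- dNx[3, n]; B[6, i + 2] <- dNx[1, n]
    }
    w <- gp$weights[a] * gp$weights[b] * gp$weights[c]
    Ke <- Ke + t(B) %*% D %*% B * det(J) * w
  }
  Ke
}

oracle_assemble_dense <- function(mesh, materials) {
  ndof <- 3 * nrow(mesh$nodes)
  K <- matrix(0, ndof, ndof)
  for (e in seq_len(nrow(mesh$elements))) {
    m <- materials[[mesh$element_layer[e]]]
    Ke <- oracle_element_stiffness(mesh$nodes[mesh$elements[e, ], ],
                                   m$young_modulus, m$poisson_ratio)
    dofs <- as.vector(t(cbind(3 * (mesh$elements[e, ] - 1) + 1,
                              3 * (mesh$elements[e, ] - 1) + 2,
                              3 * mesh$elements[e, ])))
    K[dofs, dofs] <- K[dofs, dofs] + Ke
  }
  K
}

oracle_solve_dense <- function(K, f, constrained) {
  free <- setdiff(seq_len(nrow(K)), constrained)
  u <- numeric(nrow(K))
  u[free] <- solve(K[free, free], f[free])
  u
}
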