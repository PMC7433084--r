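test_that("element stiffness has six rigid-body modes and scales with E", {
  X <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  X <- X[c(1, 2, 4, 3, 5, 6, 8, 7), ] # package node ordering
  for (nu in c(0, 0.3)) {
    Ke <- element_stiffness(X, material_spec("m", 1, nu))
    expect_equal(Ke, t(Ke), tolerance = 1e-14)
    ev <- eigen(Ke, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sum(abs(ev) < 1e-8 * max(ev)), 6L) # rank 18 of 24
  }
  K1 <- element_stiffness(X, material_spec("m", 1, 0.25))
  K2 <- element_stiffness(X, material_spec("m", 2, 0.25))
  expect_equal(K2, 2 * K1, tolerance = 1e-15)
})

test_that("element stiffness matches the dense quadrature oracle entry-wise", {
  X <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  X <- X[c(1, 2, 4, 3, 5, 6, 8, 7), ]
  for (case in list(c(1, 0), c(17000, 0.3), c(700, 0.25))) {
    Ke <- element_stiffness(X, material_spec("m", case[1], case[2]))
    Ko <- oracle_element_stiffness(X, case[1], case[2])
    expect_lt(max(abs(Ke - Ko)) / max(abs(Ko)), 1e-8)
  }
  # non-unit anisotropic box, as in the production voxel mesh
  Xs <- X %*% diag(c(0.4, 0.4, 0.15))
  Ke <- element_stiffness(Xs, material_spec("m", 17000, 0.3))
  Ko <- oracle_element_stiffness(Xs, 17000, 0.3)
  expect_lt(max(abs(Ke - Ko)) / max(abs(Ko)), 1e-8)
})

test_that("inverted elements are rejected", {
  X <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  X <- X[c(1, 2, 4, 3, 5, 6, 8, 7), ]
  X[, 3] <- -X[, 3] # flips orientation
  expect_error(element_stiffness(X, material_spec("m", 1, 0.3)), "inverted")
})

test_that("assembly matches dense brute force and keeps rigid-body modes", {
  mesh <- tiny_mesh(2, 1, 1, vs = c(0.5, 1, 2), plate_layers = 0)
  mats <- list(trabecular = material_spec("t", 700, 0.3))
  sys <- assemble_system(mesh, mats)
  Ko <- oracle_assemble_dense(mesh, mats)
  expect_lt(max(abs(as.matrix(sys$K) - Ko)) / max(abs(Ko)), 1e-8)
  # one element: global equals element matrix (modulo the node permutation
  # between lattice numbering and element-local ordering)
  m1 <- tiny_mesh(1, 1, 1)
  s1 <- assemble_system(m1, mats)
  K1 <- element_stiffness(m1$nodes[m1$elements[1, ], ], mats$trabecular)
  gd <- as.vector(t(cbind(3 * (m1$elements[1, ] - 1) + 1,
                          3 * (m1$elements[1, ] - 1) + 2,
                          3 * m1$elements[1, ])))
  expect_lt(max(abs(as.matrix(s1$K)[gd, gd] - K1)) / max(abs(K1)), 1e-12)
  # rigid translations and rotations are in the null space
  mesh2 <- tiny_mesh(2, 2, 2, plate_layers = 1)
  sys2 <- assemble_system(mesh2, list(plate = material_spec("p", 17000, 0.3),
                                      trabecular = material_spec("t", 700, 0.3)))
  n <- nrow(mesh2$nodes)
  modes <- list(
    cbind(rep(1, n), 0, 0),
    cbind(0, rep(1, n), 0),
    cbind(0, 0, rep(1, n)),
    cbind(-mesh2$nodes[, 2], mesh2$nodes[, 1], 0),      # rotation about z
    cbind(mesh2$nodes[, 3], 0, -mesh2$nodes[, 1]),      # rotation about y
    cbind(0, -mesh2$nodes[, 3], mesh2$nodes[, 2]))      # rotation about x
  scale <- max(abs(sys2$K))
  for (md in modes) {
    u <- as.vector(t(md))
    expect_lt(max(abs(as.numeric(sys2$K %*% u))) / (scale * max(abs(u))), 1e-8)
  }
  expect_error(assemble_system(mesh2, list(plate = material_spec("p", 1, 0))),
               "unknown layer")
})

test_that("boundary conditions fill loads, constrain the base, and check inputs", {
  cfg <- model_config(label = "intact")
  mesh <- build_hex_mesh(voxelize(cfg))
  sets <- extract_node_sets(mesh, cfg)
  sys <- assemble_system(mesh)
  sys <- apply_boundary_conditions(sys, sets)
  fz <- sum(sys$load[seq(3, sys$n_dofs, 3)])
  expect_equal(fz, 147, tolerance = 1e-9)          # downward (+z) resultant
  expect_equal(sum(sys$load[seq(1, sys$n_dofs, 3)]), 0)
  expect_equal(sum(sys$load[seq(2, sys$n_dofs, 3)]), 0)
  expect_equal(length(sys$constrained_dofs), 3L * 41L * 41L)
  # doubling the force doubles the load vector exactly
  cfg2 <- model_config(load_case = load_case(total_force = 294))
  sets2 <- extract_node_sets(mesh, cfg2)
  sys2 <- apply_boundary_conditions(assemble_system(mesh), sets2)
  expect_equal(sys2$load, 2 * sys$load, tolerance = 1e-15)
  # empty bottom set errors before any solve
  empty_sets <- sets; empty_sets$bottom_surface <- integer(0)
  expect_error(apply_boundary_conditions(assemble_system(mesh), empty_sets),
               "singular")
  expect_error(solve_system(assemble_system(mesh)), "no constraints")
})

test_that("solved displacements match the dense oracle on tiny meshes", {
  mesh <- tiny_mesh(2, 2, 2, vs = c(0.5, 0.5, 0.25), plate_layers = 1)
  mats <- list(plate = material_spec("p", 17000, 0.3, 135),
               trabecular = material_spec("t", 700, 0.3))
  sys <- assemble_system(mesh, mats)
  bottom <- which(mesh$nodes[, 3] == max(mesh$nodes[, 3]))
  cdof <- sort(c(3L * (bottom - 1L) + 1L, 3L * (bottom - 1L) + 2L,
                 3L * bottom))
  f <- numeric(sys$n_dofs)
  top <- which(mesh$nodes[, 3] == 0)
  f[3L * top] <- 147 / length(top)
  sys$constrained_dofs <- cdof
  sys$load <- f
  u <- solve_system(sys)
  Ko <- oracle_assemble_dense(mesh, mats)
  uo <- oracle_solve_dense(Ko, f, cdof)
  expect_lt(max(abs(as.vector(t(u$u)) - uo)) / max(abs(uo)), 1e-8)
})

test_that("solution is linear in the load and zero without load", {
  cfg1 <- small_config(force = 147)
  cfg2 <- small_config(force = 294)
  u1 <- fe_solve(cfg1)$displacement$u
  u2 <- fe_solve(cfg2)$displacement$u
  expect_lt(max(abs(u2 - 2 * u1)) / max(abs(u1)), 1e-6)
  # zero load -> zero displacement
  mesh <- tiny_mesh(2, 2, 2)
  sys <- assemble_system(mesh, list(trabecular = material_spec("t", 700, 0.3)))
  bottom <- which(mesh$nodes[, 3] == max(mesh$nodes[, 3]))
  sys$constrained_dofs <- sort(c(3L * (bottom - 1L) + 1L,
                                 3L * (bottom - 1L) + 2L, 3L * bottom))
  u0 <- solve_system(sys)
  expect_equal(max(abs(u0$u)), 0)
})

test_that("PCG and the direct factorisation agree", {
  cfg <- suppressWarnings(small_config(spacing = 2, trab = 1.2))
  mesh <- build_hex_mesh(voxelize(cfg))
  sets <- extract_node_sets(mesh, cfg)
  sys <- apply_boundary_conditions(assemble_system(mesh), sets)
  ud <- solve_system(sys, direct_limit = .Machine$integer.max)
  ui <- solve_system(sys, direct_limit = 0, tol = 1e-10)
  expect_equal(ud$method, "sparse_cholesky")
  expect_equal(ui$method, "jacobi_pcg")
  expect_lt(max(abs(ud$u - ui$u)) / max(abs(ud$u)), 1e-6)
  # reactions balance the applied load
  expect_equal(ui$reaction_force[3], -147, tolerance = 1e-5)
})

test_that("reaction forces balance the applied load", {
  fit <- fe_solve(small_config())
  expect_equal(fit$displacement$reaction_force[3], -147, tolerance = 1e-5)
  expect_lt(abs(fit$displacement$reaction_force[1]), 1e-5 * 147)
  expect_lt(abs(fit$displacement$reaction_force[2]), 1e-5 * 147)
})
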