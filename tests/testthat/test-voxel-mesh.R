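test_that("voxelizing the default block gives the expected grid and layers", {
  g <- voxelize(model_config(label = "intact"))
  expect_equal(g$dims, c(40L, 40L, 54L))
  expect_equal(sum(g$data == 3), 0L)               # no voids when intact
  # top two vertical element layers are plate, the rest trabecular
  expect_true(all(g$data[, , 1:2] == 2))
  expect_true(all(g$data[, , 3:54] == 1))
  # realised voxel sizes cover the block exactly
  expect_equal(g$dims * g$voxel_size, c(16, 16, 8), tolerance = 1e-12)
})

test_that("voxelized void volume approaches the analytic cylinder", {
  # one isolated 1 mm hole in a small block, 0.1 mm voxels
  st <- layer_stack(plate_thickness = 0.3, trabecular_thickness = 7.7,
                    lateral_extent_x = 4, lateral_extent_y = 4,
                    plate_material = material_spec("p", 17000, 0.3, 135),
                    trabecular_material = material_spec("t", 700, 0.3))
  cfg <- model_config(
    layer_stack = st,
    hole_pattern = hole_pattern(spacing = 10, defect_extent_x = 1.5,
                                defect_extent_y = 1.5),
    voxel_size_lateral = 0.1, voxel_size_vertical = 0.1)
  g <- voxelize(cfg)
  void_vol <- sum(g$data == 3) * prod(g$voxel_size)
  expect_equal(void_vol, pi * 0.5^2 * 4, tolerance = 0.05)
})

test_that("structured mesh node and element counts are exact", {
  m <- tiny_mesh(2, 2, 2)
  expect_equal(nrow(m$elements), 8L)
  expect_equal(nrow(m$nodes), 27L)
  m1 <- tiny_mesh(1, 1, 1)
  expect_equal(nrow(m1$elements), 1L)
  expect_equal(nrow(m1$nodes), 8L)
  # degenerate all-solid grid voxel count
  expect_equal(sum(solid_grid(c(2, 2, 2))$data == 1), 8L)
})

test_that("node dedup bound and volume conservation hold", {
  cfg <- suppressWarnings(small_config(spacing = 2))
  g <- voxelize(cfg)
  m <- build_hex_mesh(g)
  d <- g$dims
  expect_lte(nrow(m$nodes), prod(d + 1L))
  # fully solid grid attains the bound
  ms <- build_hex_mesh(solid_grid(c(3, 4, 5)))
  expect_equal(nrow(ms$nodes), 4L * 5L * 6L)
  # element volumes sum to solid voxel volume (congruent boxes)
  nsolid <- sum(g$data == 1 | g$data == 2)
  expect_equal(nrow(m$elements) * prod(g$voxel_size),
               nsolid * prod(g$voxel_size), tolerance = 1e-12)
})

test_that("every study configuration is face-connected at the fast preset", {
  for (cfg in make_paper_configs(suppressWarnings(
    model_config(hole_pattern = hole_pattern(spacing = 1))))) {
    g <- voxelize(cfg)
    expect_no_error(build_hex_mesh(g))
  }
})

test_that("edge-connected voxels are rejected as a discontinuity", {
  lab <- array(0L, c(2, 2, 1)); lab[1, 1, 1] <- 1L; lab[2, 2, 1] <- 1L
  expect_error(build_hex_mesh(voxel_grid(lab, c(1, 1, 1))),
               class = "mesh_discontinuity")
  # face-connected pair is fine
  lab2 <- array(0L, c(2, 2, 1)); lab2[1, 1, 1] <- 1L; lab2[2, 1, 1] <- 1L
  expect_no_error(build_hex_mesh(voxel_grid(lab2, c(1, 1, 1))))
})

test_that("node sets carry exact equilibrium bookkeeping", {
  cfg <- model_config(label = "intact")
  mesh <- build_hex_mesh(voxelize(cfg))
  sets <- extract_node_sets(mesh, cfg)
  expect_length(sets$loaded_nodes, 41L * 41L)
  expect_equal(sum(sets$force_shares), 147, tolerance = 1e-12)
  expect_length(intersect(sets$top_surface, sets$bottom_surface), 0L)
  # patch load: footprint restricted, still sums exactly
  cfgp <- model_config(load_case = load_case(147, "uniform_patch",
                                             patch_radius = 3))
  setsp <- extract_node_sets(mesh, cfgp)
  expect_lt(length(setsp$loaded_nodes), length(sets$loaded_nodes))
  expect_equal(sum(setsp$force_shares), 147, tolerance = 1e-12)
  # hertzian profile: higher central pressure than uniform patch
  cfgh <- model_config(load_case = load_case(147, "hertzian_patch",
                                             patch_radius = 3))
  setsh <- extract_node_sets(mesh, cfgh)
  expect_equal(sum(setsh$force_shares), 147, tolerance = 1e-12)
  central <- which.min(rowSums((mesh$nodes[setsh$loaded_nodes, 1:2] - 8)^2))
  expect_gt(setsh$force_shares[central], max(setsp$force_shares) * 1.2)
})

test_that("hole rims carry no traction and empty footprints error", {
  cfg <- suppressWarnings(small_config(spacing = 2))
  mesh <- build_hex_mesh(voxelize(cfg))
  sets <- extract_node_sets(mesh, cfg)
  # nodes whose entire top-face neighbourhood is void get zero share:
  # a node strictly inside a hole mouth is not in loaded_nodes
  centers <- generate_hole_centers(cfg$hole_pattern, cfg$layer_stack)
  top <- sets$top_surface
  xy <- mesh$nodes[top, 1:2, drop = FALSE]
  r <- sqrt((xy[, 1] - centers[1, 1])^2 + (xy[, 2] - centers[1, 2])^2)
  inside <- top[r < cfg$hole_pattern$hole_diameter / 2 -
                  max(mesh$voxel_size[1:2])]
  if (length(inside))
    expect_length(intersect(inside, sets$loaded_nodes), 0L)
  expect_equal(sum(sets$force_shares), 147, tolerance = 1e-12)
  # a patch radius smaller than half a voxel catches no face centroid
  cfg0 <- model_config(load_case = load_case(147, "uniform_patch",
                                             patch_radius = 1e-6))
  expect_error(extract_node_sets(build_hex_mesh(voxelize(model_config())),
                                 cfg0), "footprint")
})

test_that("too-coarse vertical voxels are refused", {
  expect_error(model_config(voxel_size_vertical = 0.16),
               "2 elements")
})
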