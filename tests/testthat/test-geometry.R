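test_that("hole packing reproduces the enumerated square-grid counts", {
  st <- layer_stack() # 16 x 16 mm block, defect 8 x 8 defaults
  cases <- list( # spacing, expected hole count (edge-to-edge, d = 1 mm)
    list(10, 1),   # only the defect centre fits
    list(5, 4),    # pitch 6 mm -> 2 x 2
    list(1, 25))   # pitch 2 mm -> 5 x 5
  for (cs in cases) {
    centers <- generate_hole_centers(hole_pattern(spacing = cs[[1]]), st)
    expect_equal(nrow(centers), cs[[2]], info = sprintf("spacing %g", cs[[1]]))
    # centres stay in the defect rectangle, centred on the block
    expect_true(all(centers[, 1] >= 4 & centers[, 1] <= 12))
    expect_true(all(centers[, 2] >= 4 & centers[, 2] <= 12))
  }
})

test_that("edge-to-edge nearest-neighbour centre distance is spacing + diameter", {
  st <- layer_stack()
  for (sp in c(1, 2.5, 5)) {
    centers <- generate_hole_centers(hole_pattern(spacing = sp), st)
    if (nrow(centers) < 2) next
    d <- as.matrix(dist(centers))
    diag(d) <- Inf
    expect_equal(min(d), sp + 1, tolerance = 1e-12)
  }
})

test_that("hole count is non-increasing in spacing", {
  st <- layer_stack()
  counts <- vapply(c(1, 1.5, 2, 2.5, 3, 4, 5), function(sp)
    nrow(generate_hole_centers(hole_pattern(spacing = sp), st)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("hex grid packs and an impossible pattern signals empty-pattern", {
  st <- layer_stack()
  hexc <- generate_hole_centers(
    hole_pattern(spacing = 2, arrangement = "hex_grid"), st)
  sqc <- generate_hole_centers(hole_pattern(spacing = 2), st)
  expect_gt(nrow(hexc), 0)
  # hex rows are closer than square rows, so hex packs at least as many
  expect_gte(nrow(hexc), nrow(sqc))
  tiny <- layer_stack(lateral_extent_x = 3, lateral_extent_y = 3)
  expect_error(
    generate_hole_centers(hole_pattern(spacing = 1, defect_extent_x = 0.2,
                                       defect_extent_y = 0.2,
                                       hole_diameter = 0.5), tiny),
    class = "empty_hole_pattern")
})

test_that("membership partitions space and respects the hole depth", {
  cfg <- model_config(hole_pattern = hole_pattern(spacing = 3)) |>
    suppressWarnings()
  # hole axis through the block centre (3 mm spacing grid has a centre hole)
  expect_equal(geometry_membership(c(8, 8, 0.1), cfg), "hole_void")
  expect_equal(geometry_membership(c(8, 8, 2), cfg), "hole_void")
  expect_equal(geometry_membership(c(8, 8, 5), cfg), "trabecular")
  expect_equal(geometry_membership(c(1, 1, 0.1), cfg), "plate")
  expect_equal(geometry_membership(c(1, 1, 5), cfg), "trabecular")
  expect_equal(geometry_membership(c(-1, 1, 5), cfg), "outside")
  # every sampled point gets exactly one region
  set.seed(7)
  pts <- cbind(runif(500, -2, 18), runif(500, -2, 18), runif(500, -1, 9))
  m <- geometry_membership(pts, cfg)
  expect_true(all(m %in% c("plate", "trabecular", "hole_void", "outside")))
  expect_equal(length(m), 500L)
  # intact: no voids anywhere
  m0 <- geometry_membership(pts, model_config())
  expect_false(any(m0 == "hole_void"))
})

test_that("the eight study configurations differ only in hole spacing", {
  configs <- make_paper_configs(suppressWarnings(
    model_config(hole_pattern = hole_pattern(spacing = 1))))
  expect_length(configs, 8L)
  expect_equal(sum(vapply(configs, function(c) is.null(c$hole_pattern), TRUE)),
               1L)
  expect_false(anyDuplicated(names(configs)) > 0)
  spacings <- na.omit(vapply(configs, function(c)
    if (is.null(c$hole_pattern)) NA_real_ else c$hole_pattern$spacing, 0))
  expect_equal(sort(as.numeric(spacings)), c(1, 1.5, 2, 2.5, 3, 4, 5))
  for (c in configs) {
    expect_equal(c$load_case$total_force, 147)
    if (!is.null(c$hole_pattern)) expect_equal(c$hole_pattern$hole_depth, 4)
  }
})

test_that("config validation enforces mesh and geometry invariants", {
  expect_error(model_config(voxel_size_vertical = 0.2),
               "2 elements through the plate")
  expect_error(material_spec("m", -1, 0.3), "young_modulus")
  expect_error(material_spec("m", 1, 0.5), "poisson_ratio")
  expect_error(hole_pattern(spacing = 0.5, spacing_convention = "center_to_center"),
               "exceed")
  expect_error(load_case(application = "uniform_patch"), "patch_radius")
  expect_warning(model_config(hole_pattern = hole_pattern(spacing = 2)),
                 "coarsely resolved")
  expect_error(suppressWarnings(model_config(
    hole_pattern = hole_pattern(spacing = 2, hole_depth = 10))),
    "stack height")
})

test_that("model configs survive YAML and JSON round trips", {
  cfg <- suppressWarnings(model_config(
    hole_pattern = hole_pattern(spacing = 2.5),
    load_case = load_case(total_force = 147, application = "uniform_patch",
                          patch_radius = 5),
    label = "roundtrip"))
  for (ext in c("yaml", "json")) {
    path <- file.path(tempdir(), paste0("cfg.", ext))
    write_model_config(cfg, path)
    back <- suppressWarnings(read_model_config(path))
    expect_equal(back[setdiff(names(back), "layer_stack")],
                 cfg[setdiff(names(cfg), "layer_stack")])
    expect_equal(unclass(back$layer_stack$plate_material),
                 unclass(cfg$layer_stack$plate_material))
  }
})

test_that("holes never overlap, so the total void volume is count * cylinder", {
  st <- layer_stack()
  for (sp in c(1, 2.5, 5)) {
    for (arr in c("square_grid", "hex_grid")) {
      pat <- hole_pattern(spacing = sp, arrangement = arr)
      centers <- generate_hole_centers(pat, st)
      if (nrow(centers) > 1) {
        d <- as.matrix(dist(centers)); diag(d) <- Inf
        # disjoint cylinders: union volume = n * pi r^2 depth exactly
        expect_gt(min(d), pat$hole_diameter * (1 + 1e-9))
      }
    }
  }
})
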