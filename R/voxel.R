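#' Voxel grid container
#'
#' A labelled or grayscale 3-D voxel volume. `data` is an array indexed
#' `[i, j, k]` for x, y, z (z downward, slice k = 1 at the articular
#' surface). Label volumes use the integer codes 0 background/outside,
#' 1 trabecular, 2 plate, 3 hole void; grayscale volumes hold arbitrary
#' numeric intensities.
#'
#' @param data 3-D numeric array.
#' @param voxel_size Numeric length-3 voxel size in mm (x, y, z).
#' @param kind `"labels"` or `"grayscale"`.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(data, voxel_size, kind = c("labels", "grayscale")) {
  kind <- match.arg(kind)
  stopifnot(is.array(data), length(dim(data)) == 3L,
            all(dim(data) >= 1L),
            is.numeric(voxel_size), length(voxel_size) == 3L,
            all(voxel_size > 0))
  structure(list(data = data, dims = dim(data),
                 voxel_size = as.numeric(voxel_size), kind = kind),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %s, %d x %d x %d voxels of %g x %g x %g mm\n",
              x$kind, x$dims[1], x$dims[2], x$dims[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

# label codes shared across the package
LABEL_BACKGROUND <- 0L
LABEL_TRABECULAR <- 1L
LABEL_PLATE <- 2L
LABEL_VOID <- 3L

label_code <- function(region) {
  unname(c(outside = LABEL_BACKGROUND, trabecular = LABEL_TRABECULAR,
           plate = LABEL_PLATE, hole_void = LABEL_VOID)[region])
}

#' Voxelize a model configuration
#'
#' Rasterises the parametric geometry onto a regular grid: each voxel takes
#' the region of [geometry_membership()] at its centroid. The grid dimension
#' along each axis is `ceiling(extent / voxel_size)` with the realised voxel
#' size `extent / dims`, so the grid covers the block exactly.
#'
#' @param config A [model_config()].
#' @return A labelled [voxel_grid()].
#' @export
voxelize <- function(config) {
  stopifnot(inherits(config, "model_config"))
  st <- config$layer_stack
  ex <- c(st$lateral_extent_x, st$lateral_extent_y, total_height(st))
  nominal <- c(config$voxel_size_lateral, config$voxel_size_lateral,
               config$voxel_size_vertical)
  dims <- pmax(1L, as.integer(ceiling(ex / nominal - 1e-9)))
  vs <- ex / dims
  if (st$plate_thickness / vs[3] < 2 - 1e-9)
    stop("realised vertical voxel size leaves fewer than 2 elements through the plate")
  xc <- (seq_len(dims[1]) - 0.5) * vs[1]
  yc <- (seq_len(dims[2]) - 0.5) * vs[2]
  zc <- (seq_len(dims[3]) - 0.5) * vs[3]
  # layer from depth alone, then carve holes (vectorized per hole)
  lab_z <- ifelse(zc <= st$plate_thickness, LABEL_PLATE, LABEL_TRABECULAR)
  labels <- array(rep(lab_z, each = dims[1] * dims[2]), dim = dims)
  if (!is.null(config$hole_pattern)) {
    pat <- config$hole_pattern
    centers <- generate_hole_centers(pat, st)
    r2 <- (pat$hole_diameter / 2)^2
    kmax <- sum(zc <= pat$hole_depth)
    if (kmax > 0) {
      d2 <- matrix(Inf, dims[1], dims[2])
      for (h in seq_len(nrow(centers))) {
        dh <- outer((xc - centers[h, 1])^2, (yc - centers[h, 2])^2, `+`)
        d2 <- pmin(d2, dh)
      }
      void_xy <- d2 <= r2
      if (any(void_xy)) {
        idx <- which(void_xy)
        plane <- dims[1] * dims[2]
        for (k in seq_len(kmax)) labels[idx + (k - 1) * plane] <- LABEL_VOID
      }
    }
  }
  voxel_grid(labels, vs, kind = "labels")
}

# face-connected component labelling of a logical 3-D mask, vectorized
# frontier BFS; returns integer array (0 for FALSE voxels)
face_components <- function(mask) {
  d <- dim(mask)
  comp <- array(0L, d)
  n <- prod(d)
  plane <- d[1] * d[2]
  remaining <- which(mask)
  cur <- 0L
  idx_i <- function(ix) ((ix - 1L) %% d[1]) + 1L
  idx_j <- function(ix) (((ix - 1L) %/% d[1]) %% d[2]) + 1L
  idx_k <- function(ix) ((ix - 1L) %/% plane) + 1L
  while (length(remaining)) {
    cur <- cur + 1L
    frontier <- remaining[1L]
    comp[frontier] <- cur
    while (length(frontier)) {
      i <- idx_i(frontier); j <- idx_j(frontier); k <- idx_k(frontier)
      nb <- c(frontier[i > 1] - 1L, frontier[i < d[1]] + 1L,
              frontier[j > 1] - d[1], frontier[j < d[2]] + d[1],
              frontier[k > 1] - plane, frontier[k < d[3]] + plane)
      nb <- unique(nb)
      nb <- nb[mask[nb] & comp[nb] == 0L]
      comp[nb] <- cur
      frontier <- nb
    }
    remaining <- remaining[comp[remaining] == 0L]
  }
  comp
}

#' Build a hexahedral mesh from a labelled voxel grid
#'
#' One 8-node hexahedral element per solid (plate or trabecular) voxel, with
#' shared nodes deduplicated on the structured node lattice. Node ordering
#' per element is the standard right-handed hexahedron (bottom face
#' counter-clockwise viewed from +z, then top face), giving a positive
#' Jacobian. The solid region must form a single face-connected component;
#' a disconnected region (e.g. a plate separated from the trabecular bed by
#' a segmentation artefact) is an error of class `mesh_discontinuity`, the
#' failure mode that breaks downstream structural analysis.
#'
#' @param grid A labelled [voxel_grid()].
#' @return An object of class `hex_mesh` with fields `nodes` (n x 3 matrix,
#'   mm), `elements` (m x 8 integer matrix of node indices),
#'   `element_layer` (character, `"plate"`/`"trabecular"`), `grid_dims`,
#'   `voxel_size`.
#' @export
build_hex_mesh <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"), grid$kind == "labels")
  d <- grid$dims
  vs <- grid$voxel_size
  solid <- grid$data == LABEL_PLATE | grid$data == LABEL_TRABECULAR
  nsolid <- sum(solid)
  if (nsolid == 0L) stop("grid contains no solid voxel")
  comp <- face_components(solid)
  ncomp <- max(comp)
  if (ncomp > 1L)
    stop(structure(class = c("mesh_discontinuity", "error", "condition"),
                   list(message = sprintf(
                     "solid region is disconnected (%d face-connected components); structural analysis would be singular",
                     ncomp), call = sys.call(-1))))
  sidx <- which(solid)
  plane <- d[1] * d[2]
  vi <- ((sidx - 1L) %% d[1]) + 1L
  vj <- (((sidx - 1L) %/% d[1]) %% d[2]) + 1L
  vk <- ((sidx - 1L) %/% plane) + 1L
  # lattice node ids (may be unused where voxels are void)
  nnx <- d[1] + 1L; nny <- d[2] + 1L
  nplane <- nnx * nny
  nid <- function(i, j, k) (k - 1L) * nplane + (j - 1L) * nnx + i
  n000 <- nid(vi, vj, vk)
  # z downward: "lower" face k, "upper" face k+1 in array order; element
  # nodes: counter-clockwise about +z on face z = z_k, then face z = z_k+1
  conn_lat <- cbind(n000, n000 + 1L, n000 + 1L + nnx, n000 + nnx)
  conn <- cbind(conn_lat, conn_lat + nplane)
  used <- sort(unique(as.vector(conn)))
  remap <- integer(nid(nnx, nny, d[3] + 1L))
  remap[used] <- seq_along(used)
  elements <- matrix(remap[conn], ncol = 8L)
  gi <- ((used - 1L) %% nnx)
  gj <- ((used - 1L) %/% nnx) %% nny
  gk <- (used - 1L) %/% nplane
  nodes <- cbind(x = gi * vs[1], y = gj * vs[2], z = gk * vs[3])
  layer <- ifelse(grid$data[sidx] == LABEL_PLATE, "plate", "trabecular")
  structure(list(nodes = nodes, elements = elements, element_layer = layer,
                 grid_dims = d, voxel_size = vs,
                 voxel_index = cbind(i = vi, j = vj, k = vk)),
            class = "hex_mesh")
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat(sprintf("<hex_mesh> %d nodes, %d elements (%d plate, %d trabecular)\n",
              nrow(x$nodes), nrow(x$elements),
              sum(x$element_layer == "plate"),
              sum(x$element_layer == "trabecular")))
  invisible(x)
}

#' Boundary node sets and nodal load shares
#'
#' Extracts the fixed bottom surface (nodes at maximal depth) and the loaded
#' top surface. Load shares are assigned by tributary area: the traction is
#' evaluated at each top element face centroid, multiplied by the face area,
#' and distributed in equal quarters to the face's four nodes; shares are
#' then rescaled so they sum to `total_force` exactly. Faces over hole
#' voids do not exist in the mesh, so hole rims carry no traction.
#'
#' @param mesh A [build_hex_mesh()] result.
#' @param config The [model_config()] the mesh came from (supplies the load
#'   case and extents).
#' @return An object of class `node_sets`: `top_surface`, `bottom_surface`
#'   (integer node indices), `loaded_nodes` (integer indices) and
#'   `force_shares` (N, downward, aligned with `loaded_nodes`).
#' @export
extract_node_sets <- function(mesh, config) {
  stopifnot(inherits(mesh, "hex_mesh"), inherits(config, "model_config"))
  z <- mesh$nodes[, 3]
  ztol <- mesh$voxel_size[3] * 1e-6
  bottom <- which(z >= max(z) - ztol)
  top <- which(z <= ztol)
  lc <- config$load_case
  # top faces: elements in voxel slice k == 1 (their face at z = 0)
  te <- which(mesh$voxel_index[, 3] == 1L)
  if (!length(te)) stop("no elements adjacent to the top surface")
  face_nodes <- mesh$elements[te, 1:4, drop = FALSE]
  fx <- (mesh$nodes[face_nodes[, 1], 1] + mesh$nodes[face_nodes[, 3], 1]) / 2
  fy <- (mesh$nodes[face_nodes[, 1], 2] + mesh$nodes[face_nodes[, 3], 2]) / 2
  area <- mesh$voxel_size[1] * mesh$voxel_size[2]
  st <- config$layer_stack
  cx <- st$lateral_extent_x / 2; cy <- st$lateral_extent_y / 2
  p <- switch(lc$application,
    uniform_full_face = rep(1, length(te)),
    uniform_patch = {
      r <- sqrt((fx - cx)^2 + (fy - cy)^2)
      as.numeric(r <= lc$patch_radius)
    },
    hertzian_patch = {
      r <- sqrt((fx - cx)^2 + (fy - cy)^2)
      ifelse(r <= lc$patch_radius,
             sqrt(pmax(0, 1 - (r / lc$patch_radius)^2)), 0)
    })
  w <- p * area
  if (sum(w) <= 0)
    stop("load footprint is empty (no top face under the traction)")
  face_force <- w * lc$total_force / sum(w)
  shares <- numeric(nrow(mesh$nodes))
  for (c in 1:4) {
    agg <- rowsum(face_force / 4, face_nodes[, c])
    ids <- as.integer(rownames(agg))
    shares[ids] <- shares[ids] + agg[, 1]
  }
  loaded <- which(shares != 0)
  # rescale for exact equilibrium bookkeeping
  shares[loaded] <- shares[loaded] * lc$total_force / sum(shares[loaded])
  structure(list(top_surface = top, bottom_surface = bottom,
                 loaded_nodes = loaded, force_shares = shares[loaded]),
            class = "node_sets")
}

#' @export
print.node_sets <- function(x, ...) {
  cat(sprintf(
    "<node_sets> %d top, %d bottom (fixed), %d loaded nodes (sum %.6g N)\n",
    length(x$top_surface), length(x$bottom_surface), length(x$loaded_nodes),
    sum(x$force_shares)))
  invisible(x)
}
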