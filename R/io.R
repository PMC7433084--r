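# Voxel-volume and mesh serialisation.

#' Write / read a voxel grid as raw binary plus JSON sidecar
#'
#' Stores the voxel data as little-endian float64 in x-fastest order next
#' to a JSON sidecar (`<path>.json`) carrying dims, voxel size (mm), kind
#' and the label map. The round trip is lossless.
#'
#' @param grid A [voxel_grid()].
#' @param path Path of the `.raw` file; the sidecar goes to `<path>.json`.
#' @return `read_voxel_raw` returns a `voxel_grid`; `write_voxel_raw`
#'   returns `path` invisibly.
#' @export
write_voxel_raw <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(grid$data), con, size = 8, endian = "little")
  sidecar <- list(dims = grid$dims, voxel_size_mm = grid$voxel_size,
                  kind = grid$kind, dtype = "float64", order = "x_fastest",
                  label_map = list(background = 0, trabecular = 1,
                                   plate = 2, void = 3))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_voxel_raw
#' @export
read_voxel_raw <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(meta$dims)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = n, size = 8, endian = "little")
  voxel_grid(array(v, dim = meta$dims), meta$voxel_size_mm, kind = meta$kind)
}

#' Write / read a voxel grid as a multi-page TIFF stack
#'
#' One 32-bit float page per z slice (top slice first). TIFF pages store
#' values in [0, 1], so intensities are mapped as `(x - offset) / scale`
#' with a power-of-two `scale`; offset, scale, voxel size and kind travel
#' in a JSON sidecar (`<path>.json`). The dyadic scale makes the round
#' trip exact for label volumes (small integers); arbitrary float64
#' intensities are stored at float32 precision — use the raw format when
#' full precision matters.
#'
#' @param grid A [voxel_grid()].
#' @param path Path of the `.tif` file.
#' @return `read_voxel_tiff` returns a `voxel_grid`; `write_voxel_tiff`
#'   returns `path` invisibly.
#' @export
write_voxel_tiff <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  lo <- min(grid$data)
  span <- max(grid$data) - lo
  scale <- 2^ceiling(log2(max(span * (1 + 1e-9), 1)))
  # tiff wants row x col matrices in [0, 1]; y as rows, x as cols per slice
  slices <- lapply(seq_len(grid$dims[3]), function(k) {
    m <- t((grid$data[, , k] - lo) / scale)
    storage.mode(m) <- "double"
    m
  })
  tiff::writeTIFF(slices, path, bits.per.sample = 32)
  jsonlite::write_json(list(dims = grid$dims,
                            voxel_size_mm = grid$voxel_size,
                            kind = grid$kind,
                            offset = lo, scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_voxel_tiff
#' @export
read_voxel_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  d <- meta$dims
  a <- array(0, dim = d)
  for (k in seq_len(d[3])) a[, , k] <- t(pages[[k]]) * meta$scale + meta$offset
  if (meta$kind == "labels") a <- array(as.integer(round(a)), dim = d)
  voxel_grid(a, meta$voxel_size_mm, kind = meta$kind)
}

#' Export a mesh (and optional fields) as legacy VTK
#'
#' Writes an ASCII legacy VTK unstructured grid of the hexahedral mesh with
#' the element layer as cell data, plus any per-element fields supplied
#' (e.g. von Mises stress) and optional per-node displacement vectors.
#' Readable by ParaView and pyvista.
#'
#' @param mesh A [build_hex_mesh()] result.
#' @param path Output `.vtk` path.
#' @param cell_data Named list of numeric per-element vectors.
#' @param point_vectors Optional n_nodes x 3 matrix (e.g. displacements).
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, cell_data = list(), point_vectors = NULL) {
  stopifnot(inherits(mesh, "hex_mesh"))
  nn <- nrow(mesh$nodes); ne <- nrow(mesh$elements)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# vtk DataFile Version 3.0")
  w("voxel hexahedral mesh")
  w("ASCII")
  w("DATASET UNSTRUCTURED_GRID")
  w("POINTS %d double", nn)
  writeLines(paste(mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  w("CELLS %d %d", ne, ne * 9L)
  conn0 <- mesh$elements - 1L  # VTK is 0-based; VTK_HEXAHEDRON ordering
  writeLines(paste(8L, conn0[, 1], conn0[, 2], conn0[, 3], conn0[, 4],
                   conn0[, 5], conn0[, 6], conn0[, 7], conn0[, 8]), con)
  w("CELL_TYPES %d", ne)
  writeLines(as.character(rep(12L, ne)), con)
  w("CELL_DATA %d", ne)
  w("SCALARS layer int 1")
  w("LOOKUP_TABLE default")
  writeLines(as.character(ifelse(mesh$element_layer == "plate", 2L, 1L)), con)
  for (nm in names(cell_data)) {
    stopifnot(length(cell_data[[nm]]) == ne)
    w("SCALARS %s double 1", nm)
    w("LOOKUP_TABLE default")
    writeLines(as.character(cell_data[[nm]]), con)
  }
  if (!is.null(point_vectors)) {
    stopifnot(nrow(point_vectors) == nn, ncol(point_vectors) == 3)
    w("POINT_DATA %d", nn)
    w("VECTORS displacement double")
    writeLines(paste(point_vectors[, 1], point_vectors[, 2],
                     point_vectors[, 3]), con)
  }
  invisible(path)
}
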