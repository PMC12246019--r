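#' Write a surface mesh as binary little-endian PLY
#'
#' Vertices carry a per-vertex integer region (bone label) property;
#' faces carry the per-triangle region.
#'
#' @param mesh a \code{surface_mesh}
#' @param path output .ply path
#' @export
write_ply <- function(mesh, path) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$triangles)
  vreg <- mesh$vertex_region
  if (is.null(vreg)) vreg <- rep(0L, nv)
  vreg[is.na(vreg)] <- 0L
  header <- c(
    "ply", "format binary_little_endian 1.0",
    "comment suturemech surface",
    paste("element vertex", nv),
    "property float x", "property float y", "property float z",
    "property int region",
    paste("element face", nf),
    "property list uchar int vertex_indices",
    "property int region",
    "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con)
  for (i in seq_len(nv)) {
    writeBin(as.numeric(mesh$vertices[i, ]), con, size = 4,
             endian = "little")
    writeBin(as.integer(vreg[i]), con, size = 4, endian = "little")
  }
  for (i in seq_len(nf)) {
    writeBin(as.raw(3), con)
    writeBin(as.integer(mesh$triangles[i, ] - 1L), con, size = 4,
             endian = "little")
    writeBin(as.integer(mesh$region[i]), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a PLY surface written by \code{\link{write_ply}}
#' @param path .ply path
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  nv <- nf <- NULL
  repeat {
    line <- readLines(con, n = 1)
    if (startsWith(line, "element vertex"))
      nv <- as.integer(strsplit(line, " ")[[1]][3])
    if (startsWith(line, "element face"))
      nf <- as.integer(strsplit(line, " ")[[1]][3])
    if (line == "end_header") break
  }
  verts <- matrix(0, nv, 3); vreg <- integer(nv)
  for (i in seq_len(nv)) {
    verts[i, ] <- readBin(con, numeric(), n = 3, size = 4,
                          endian = "little")
    vreg[i] <- readBin(con, integer(), n = 1, size = 4, endian = "little")
  }
  tris <- matrix(0L, nf, 3); freg <- integer(nf)
  for (i in seq_len(nf)) {
    readBin(con, raw(), n = 1)
    tris[i, ] <- readBin(con, integer(), n = 3, size = 4,
                         endian = "little") + 1L
    freg[i] <- readBin(con, integer(), n = 1, size = 4, endian = "little")
  }
  surface_mesh(verts, tris, freg, vreg)
}

#' Write a tet mesh (and optional results) as legacy ASCII VTK
#'
#' @param mesh a \code{tet_mesh}
#' @param path output .vtk path
#' @param point_data optional named list of per-node vectors/matrices
#' @param cell_data optional named list of per-tet vectors
#' @export
write_vtk <- function(mesh, path, point_data = NULL, cell_data = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  writeLines(c("# vtk DataFile Version 3.0", "suturemech tet mesh",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", n, "double")), con)
  utils::write.table(mesh$nodes, con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(paste("CELLS", m, 5 * m), con)
  utils::write.table(cbind(4L, mesh$tets - 1L), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(paste("CELL_TYPES", m), con)
  writeLines(as.character(rep(10L, m)), con)
  writeLines(paste("CELL_DATA", m), con)
  writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(mesh$region), con)
  if (!is.null(cell_data)) {
    for (nm in names(cell_data)) {
      writeLines(c(paste("SCALARS", nm, "double 1"),
                   "LOOKUP_TABLE default"), con)
      writeLines(as.character(cell_data[[nm]]), con)
    }
  }
  if (!is.null(point_data)) {
    writeLines(paste("POINT_DATA", n), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v) && ncol(v) == 3) {
        writeLines(paste("VECTORS", nm, "double"), con)
        utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
      } else {
        writeLines(c(paste("SCALARS", nm, "double 1"),
                     "LOOKUP_TABLE default"), con)
        writeLines(as.character(v), con)
      }
    }
  }
  invisible(path)
}
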