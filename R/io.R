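#' Export a mesh (with optional cell data) to legacy VTK
#'
#' ASCII legacy VTK unstructured grid (cell type 10 = tetrahedron). Cell data
#' arrays (e.g. a conductivity field or a reconstruction) are written as
#' per-cell scalars.
#'
#' @param mesh an `eit_mesh`.
#' @param path output file (.vtk).
#' @param cell_data named list of per-element numeric vectors.
#' @export
write_vtk <- function(mesh, path, cell_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "tetrahedral tank mesh (mm)", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", mesh$n_nodes)), con)
  writeLines(sprintf("%g %g %g", mesh$nodes[, 1], mesh$nodes[, 2],
                     mesh$nodes[, 3]), con)
  writeLines(sprintf("CELLS %d %d", mesh$n_elements, 5L * mesh$n_elements), con)
  writeLines(sprintf("4 %d %d %d %d", mesh$tets[, 1] - 1L, mesh$tets[, 2] - 1L,
                     mesh$tets[, 3] - 1L, mesh$tets[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", mesh$n_elements), con)
  writeLines(rep("10", mesh$n_elements), con)
  if (length(cell_data) > 0) {
    writeLines(sprintf("CELL_DATA %d", mesh$n_elements), con)
    for (nm in names(cell_data)) {
      v <- cell_data[[nm]]
      stopifnot(length(v) == mesh$n_elements)
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
                 con)
      writeLines(sprintf("%g", v), con)
    }
  }
  invisible(path)
}

#' Export a mesh in Gmsh MSH 2.2 ASCII format
#' @param mesh an `eit_mesh`.
#' @param path output file (.msh).
#' @export
write_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
               "$Nodes", sprintf("%d", mesh$n_nodes)), con)
  writeLines(sprintf("%d %g %g %g", seq_len(mesh$n_nodes), mesh$nodes[, 1],
                     mesh$nodes[, 2], mesh$nodes[, 3]), con)
  writeLines(c("$EndNodes", "$Elements", sprintf("%d", mesh$n_elements)), con)
  writeLines(sprintf("%d 4 2 0 1 %d %d %d %d", seq_len(mesh$n_elements),
                     mesh$tets[, 1], mesh$tets[, 2], mesh$tets[, 3],
                     mesh$tets[, 4]), con)
  writeLines("$EndElements", con)
  invisible(path)
}
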