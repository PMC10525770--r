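# Minimal ASCII writers for the standard exchange formats (STL for surface
# meshes, legacy VTK for meshes/point clouds with data arrays, CSV for
# centerlines). ASCII keeps the artifacts diffable and viewer-compatible.

#' Write a surface mesh as ASCII STL
#'
#' @param mesh list with `vertices`, `faces`, `normals` (e.g.
#'   `geometry$surface`).
#' @param path output path.
#' @param name solid name written into the file.
#' @return The path, invisibly.
#' @export
write_stl <- function(mesh, path, name = "cabvort") {
  v <- mesh$vertices; f <- mesh$faces; n <- mesh$normals
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("solid", name), con)
  tri <- sprintf(
    "facet normal %.9g %.9g %.9g\n outer loop\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n endloop\nendfacet",
    n[, 1], n[, 2], n[, 3],
    v[f[, 1], 1], v[f[, 1], 2], v[f[, 1], 3],
    v[f[, 2], 1], v[f[, 2], 2], v[f[, 2], 3],
    v[f[, 3], 1], v[f[, 3], 2], v[f[, 3], 3])
  writeLines(tri, con)
  writeLines(paste("endsolid", name), con)
  invisible(path)
}

#' Write a surface mesh as legacy-VTK polydata
#'
#' Optionally attaches per-face (cell) scalar arrays, e.g. WSS magnitude or
#' branch labels.
#'
#' @param mesh list with `vertices`, `faces`.
#' @param path output path.
#' @param cell_data named list of per-face numeric vectors.
#' @return The path, invisibly.
#' @export
write_vtk_polydata <- function(mesh, path, cell_data = NULL) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "cabvort surface", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", nrow(v))), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(f), 4L * nrow(f)), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  if (!is.null(cell_data) && length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", nrow(f)), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.9g", as.numeric(cell_data[[nm]])), con)
    }
  }
  invisible(path)
}

#' Write a flow snapshot as legacy-VTK structured/unstructured points
#'
#' Writes the point cloud with `velocity` (vectors) and `pressure` (scalars)
#' point-data arrays, plus any extra per-point arrays (e.g. `lambda2`,
#' `vortex_id`).
#'
#' @param snapshot a [flow_snapshot()].
#' @param path output path.
#' @param point_data named list of extra per-point numeric vectors.
#' @return The path, invisibly.
#' @export
write_vtk_snapshot <- function(snapshot, path, point_data = NULL) {
  p <- snapshot$points
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("cabvort snapshot t=%g", snapshot$t), "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", nrow(p))), con)
  writeLines(sprintf("%.9g %.9g %.9g", p[, 1], p[, 2], p[, 3]), con)
  writeLines(sprintf("POINT_DATA %d", nrow(p)), con)
  writeLines("VECTORS velocity double", con)
  writeLines(sprintf("%.9g %.9g %.9g", snapshot$velocity[, 1],
                     snapshot$velocity[, 2], snapshot$velocity[, 3]), con)
  writeLines(c("SCALARS pressure double 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.9g", snapshot$pressure), con)
  if (!is.null(point_data)) {
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.9g", as.numeric(point_data[[nm]])), con)
    }
  }
  invisible(path)
}

#' Write branch centerlines as CSV
#'
#' One file with columns `branch, x, y, z, arclength`.
#'
#' @param geom a `cab_geometry`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_centerlines_csv <- function(geom, path) {
  df <- do.call(rbind, lapply(names(geom$centerlines), function(b) {
    cbind(branch = b, geom$centerlines[[b]])
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
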