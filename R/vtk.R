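#' Write cell fields to a legacy-ASCII VTK file
#'
#' Exports the fluid cells of a mask-based mesh as an unstructured grid
#' of quads with cell-data arrays, readable by ParaView/VisIt.
#'
#' @param mesh a `clot_mesh`
#' @param fields named list of numeric vectors over fluid cells
#' @param path output file
#' @return invisibly, `path`
#' @export
write_vtk <- function(mesh, fields = list(), path) {
  cells <- mesh$cells
  n <- nrow(cells)
  dx <- mesh$dx; dy <- mesh$dy
  x0 <- cells$x - dx / 2; x1 <- cells$x + dx / 2
  y0 <- cells$y - dy / 2; y1 <- cells$y + dy / 2
  px <- as.vector(rbind(x0, x1, x1, x0))   # 4 corners per cell, in order
  py <- as.vector(rbind(y0, y0, y1, y1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "clotflow fields", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", 4L * n)), con)
  writeLines(sprintf("%.9g %.9g 0", px, py), con)
  writeLines(sprintf("CELLS %d %d", n, 5L * n), con)
  base <- (seq_len(n) - 1L) * 4L
  writeLines(sprintf("4 %d %d %d %d", base, base + 1L, base + 2L, base + 3L),
             con)
  writeLines(sprintf("CELL_TYPES %d", n), con)
  writeLines(rep("9", n), con)
  if (length(fields)) {
    writeLines(sprintf("CELL_DATA %d", n), con)
    for (nmf in names(fields)) {
      v <- fields[[nmf]]
      stopifnot(length(v) == n)
      v[!is.finite(v)] <- 0
      writeLines(c(sprintf("SCALARS %s double 1", nmf),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.9g", v), con)
    }
  }
  invisible(path)
}
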