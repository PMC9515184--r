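# Legacy-VTK (ASCII) export/import of tetrahedral meshes and nodal/element
# fields, for external inspection of meshes, flow fields and lesions.

#' Write a mesh (with optional fields) to a legacy VTK file
#'
#' Writes an ASCII unstructured-grid `.vtk` file with the region label as
#' cell data; additional per-node (`point_data`) and per-element
#' (`cell_data`) scalar fields may be attached. Numeric values are written
#' with full precision so a write/read round trip reproduces the mesh
#' exactly.
#'
#' @param mesh an `ablation_mesh` (or fixture mesh).
#' @param path output file path.
#' @param point_data named list of nodal scalar vectors.
#' @param cell_data named list of element scalar vectors.
#' @return `path`, invisibly.
#' @export
write_vtk_mesh <- function(mesh, path, point_data = list(), cell_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)
  writeLines(c("# vtk DataFile Version 3.0", "ablatr mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID"), con)
  n <- mesh$n_nodes; m <- nrow(mesh$elems)
  writeLines(sprintf("POINTS %d double", n), con)
  writeLines(apply(mesh$nodes, 1, function(r) paste(fmt(r), collapse = " ")), con)
  writeLines(sprintf("CELLS %d %d", m, 5 * m), con)
  writeLines(apply(mesh$elems - 1L, 1, function(r) paste(c(4L, r), collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("10", m), con)

  regions <- sort(unique(mesh$region))
  cell_data <- c(list(region = match(mesh$region, regions)), cell_data)
  writeLines(sprintf("CELL_DATA %d", m), con)
  for (nm in names(cell_data)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
    writeLines(fmt(as.numeric(cell_data[[nm]])), con)
  }
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(fmt(as.numeric(point_data[[nm]])), con)
    }
  }
  attr(path, "region_levels") <- regions
  invisible(path)
}

#' Read a legacy VTK unstructured-grid file
#'
#' Counterpart of [write_vtk_mesh()]; reads points, tetrahedral cells and all
#' scalar fields.
#'
#' @param path file path.
#' @return list with `nodes`, `elems`, `point_data`, `cell_data`.
#' @export
read_vtk_mesh <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)[1]
  n <- as.integer(strsplit(lines[ip], " ")[[1]][2])
  nodes <- matrix(as.numeric(unlist(strsplit(lines[ip + seq_len(n)], " "))),
                  ncol = 3, byrow = TRUE)
  ic <- grep("^CELLS", lines)[1]
  m <- as.integer(strsplit(lines[ic], " ")[[1]][2])
  cells <- matrix(as.integer(unlist(strsplit(lines[ic + seq_len(m)], " "))),
                  ncol = 5, byrow = TRUE)
  stopifnot(all(cells[, 1] == 4L))
  elems <- cells[, -1, drop = FALSE] + 1L

  read_scalars <- function(start, count, stop_at) {
    out <- list()
    i <- start
    while (i <= length(lines) && !grepl(stop_at, lines[i])) {
      if (grepl("^SCALARS", lines[i])) {
        nm <- strsplit(lines[i], " ")[[1]][2]
        vals <- as.numeric(lines[i + 1 + seq_len(count)])
        out[[nm]] <- vals
        i <- i + 1 + count
      }
      i <- i + 1
    }
    out
  }
  icd <- grep("^CELL_DATA", lines)
  ipd <- grep("^POINT_DATA", lines)
  cell_data <- if (length(icd)) read_scalars(icd[1] + 1, m, "^POINT_DATA") else list()
  point_data <- if (length(ipd)) read_scalars(ipd[1] + 1, n, "$^") else list()
  list(nodes = nodes, elems = elems, point_data = point_data,
       cell_data = cell_data)
}
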