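# File round-tripping: native JSON containers for meshes and eigenbases,
# CSV recordings/layouts/solutions, legacy-ASCII VTK export, MatrixMarket
# matrix export, and YAML/JSON configuration files.
#
# CSV dialect: comma-separated, '.' decimal, mandatory header row.
# Node and element ids are 0-based on disk (the documented native format)
# and 1-based in memory.

#' Write / read a mesh in the native JSON container
#'
#' Lossless round trip of nodes, elements, tissue table, fractions, heart
#' flags and the optional lateral surface grid.  Ids are 0-based on disk.
#'
#' @param mesh an [ecgi_mesh()].
#' @param path output file.
#' @return `write_mesh_json`: the path, invisibly.  `read_mesh_json`: the
#'   mesh.
#' @export
write_mesh_json <- function(mesh, path) {
  obj <- list(
    format = "directECGI-mesh", version = 1L,
    units = list(coordinates = "cm", conductivity = "S/m"),
    nodes = unname(as.matrix(mesh$nodes)),
    elements = unname(as.matrix(mesh$elements)) - 1L,
    tissues = list(name = mesh$tissues$name,
                   conductivity = mesh$tissues$conductivity),
    fraction_tissues = colnames(mesh$fractions),
    fractions = unname(as.matrix(mesh$fractions)),
    heart = mesh$heart)
  if (!is.null(mesh$surface_grid)) {
    g <- mesh$surface_grid
    obj$surface_grid <- list(node = g$node - 1L, level = g$level,
                             sector = g$sector,
                             n_sectors = attr(g, "n_sectors"),
                             wrap = isTRUE(attr(g, "wrap")))
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_mesh_json
#' @export
read_mesh_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "directECGI-mesh"))
    stop("not a directECGI mesh container: ", path)
  grid <- NULL
  if (!is.null(obj$surface_grid)) {
    grid <- data.frame(node = as.integer(obj$surface_grid$node) + 1L,
                       level = as.integer(obj$surface_grid$level),
                       sector = as.integer(obj$surface_grid$sector))
    attr(grid, "n_sectors") <- as.integer(obj$surface_grid$n_sectors)
    attr(grid, "wrap") <- isTRUE(obj$surface_grid$wrap)
  }
  fr <- as.matrix(obj$fractions)
  colnames(fr) <- obj$fraction_tissues
  ecgi_mesh(as.matrix(obj$nodes), as.matrix(obj$elements) + 1L,
            tissue_table(obj$tissues$name, obj$tissues$conductivity),
            fr, as.logical(obj$heart), surface_grid = grid)
}

#' Write / read an eigenbasis in the native JSON container
#'
#' Eigenvalues, M-orthonormal eigenvectors, mass vector and retained mask
#' round-trip at full double precision, so the overnight pre-processing
#' phase (the eigenanalysis) can be cached and reused across beats.
#'
#' @param basis an `ecgi_basis`.
#' @param path output file.
#' @export
write_basis_json <- function(basis, path) {
  obj <- list(format = "directECGI-basis", version = 1L,
              values = basis$values,
              vectors = unname(basis$vectors),
              mass = basis$mass,
              retained = basis$retained,
              null_modes = basis$null_modes,
              null_tol = basis$null_tol,
              energy_fraction = basis$energy_fraction)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_basis_json
#' @export
read_basis_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "directECGI-basis"))
    stop("not a directECGI basis container: ", path)
  num_or_na <- function(x) if (is.null(x) || !length(x)) NA_real_ else as.numeric(x)
  structure(list(values = as.numeric(obj$values),
                 vectors = as.matrix(obj$vectors),
                 mass = as.numeric(obj$mass),
                 retained = as.logical(obj$retained),
                 null_modes = if (is.null(obj$null_modes)) integer(0)
                 else as.integer(obj$null_modes),
                 null_tol = num_or_na(obj$null_tol),
                 energy_fraction = num_or_na(obj$energy_fraction)),
            class = "ecgi_basis")
}

#' Write / read electrode recordings as CSV
#'
#' Rows are electrodes (id in the first column), columns the time samples
#' in ms order (`t1`, `t2`, ...).
#'
#' @param recordings `M x T` matrix.
#' @param path file path.
#' @export
write_recordings_csv <- function(recordings, path) {
  df <- data.frame(electrode = if (is.null(rownames(recordings)))
    seq_len(nrow(recordings)) else rownames(recordings),
    recordings, check.names = FALSE)
  colnames(df) <- c("electrode", paste0("t", seq_len(ncol(recordings))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recordings_csv
#' @export
read_recordings_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2) stop("recordings CSV needs an id column plus samples: ", path)
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(mat, 2, as.numeric))), arr.ind = TRUE)
    stop(sprintf("non-numeric recording value at row %d, column %d of %s",
                 bad[1, 1], bad[1, 2] + 1L, path))
  }
  rownames(mat) <- df[[1]]
  mat
}

#' Write / read an electrode layout as CSV
#'
#' Columns `electrode`, `node` (0-based on disk) and optionally `x`, `y`,
#' `z` positions in cm.
#'
#' @param layout an [electrode_layout()].
#' @param path file path.
#' @param mesh optional mesh; when given, node coordinates are included.
#' @export
write_layout_csv <- function(layout, path, mesh = NULL) {
  df <- data.frame(electrode = layout$electrode, node = layout$node - 1L)
  if (!is.null(mesh)) {
    p <- mesh$nodes[layout$node, , drop = FALSE]
    df$x <- p[, 1]; df$y <- p[, 2]; df$z <- p[, 3]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_layout_csv
#' @param mesh_for_read mesh used to rebuild the layout (and, when the
#'   file carries positions but no `node` column, to re-associate them).
#' @export
read_layout_csv <- function(path, mesh_for_read) {
  df <- utils::read.csv(path)
  if ("node" %in% names(df))
    electrode_layout(as.integer(df$node) + 1L, mesh_for_read, df$electrode)
  else if (all(c("x", "y", "z") %in% names(df)))
    map_electrodes_to_nodes(as.matrix(df[, c("x", "y", "z")]), mesh_for_read,
                            df$electrode)
  else stop("layout CSV needs either a 'node' or 'x','y','z' columns: ", path)
}

#' Write an epicardial (or any nodal) solution as CSV
#'
#' @param epi an `ecgi_epi`.
#' @param path file path.
#' @export
write_epicardial_csv <- function(epi, path) {
  df <- data.frame(node = epi$nodes - 1L, epi$values, check.names = FALSE)
  colnames(df) <- c("node", paste0("t", seq_len(ncol(epi$values))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_epicardial_csv
#' @export
read_epicardial_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  structure(list(nodes = as.integer(df$node) + 1L,
                 values = as.matrix(df[, -1, drop = FALSE])),
            class = "ecgi_epi")
}

#' Export a mesh (and nodal fields) to legacy ASCII VTK
#'
#' One-way export of the hexahedral grid with optional point-data arrays
#' (e.g. a reconstructed potential at one time sample) for visualization.
#'
#' @param mesh an [ecgi_mesh()].
#' @param path output `.vtk` file.
#' @param point_data named list of numeric `N`-vectors.
#' @export
write_vtk_mesh <- function(mesh, path, point_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  N <- nrow(mesh$nodes); E <- nrow(mesh$elements)
  writeLines(c("# vtk DataFile Version 3.0",
               "directECGI volume conductor", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", N)), con)
  utils::write.table(mesh$nodes, con, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("CELLS %d %d", E, 9L * E), con)
  utils::write.table(cbind(8L, mesh$elements - 1L), con,
                     row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("CELL_TYPES %d", E), con)
  writeLines(as.character(rep(12L, E)), con)   # VTK_HEXAHEDRON
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", N), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
                 con)
      writeLines(format(point_data[[nm]], digits = 12), con)
    }
  }
  invisible(path)
}

#' Export a sparse matrix in MatrixMarket coordinate format
#'
#' @param M a sparse [Matrix::Matrix()].
#' @param path output `.mtx` file.
#' @export
write_matrix_market <- function(M, path) {
  Matrix::writeMM(methods::as(M, "generalMatrix"), path)
  invisible(path)
}

#' Read a pipeline configuration file (JSON or YAML)
#'
#' The format is chosen by extension; YAML requires the `yaml` package.
#'
#' @param path configuration file.
#' @return A named list, passed to [pipeline_config()].
#' @export
read_config_file <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  if (grepl("\\.(ya?ml)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configuration needs the 'yaml' package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
}
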