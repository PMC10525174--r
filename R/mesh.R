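# Volume-conductor mesh data model: trilinear hexahedral elements with
# per-element tissue composition, outer-surface and epicardial face sets.
#
# Conventions (documented also in the native JSON container):
#  * node/element ids are 0-based on disk, 1-based in memory (R indexing);
#  * hexahedron corners follow the standard trilinear (VTK) ordering, i.e.
#    local corners 1..4 counter-clockwise on the zeta = -1 face, 5..8 the
#    corresponding corners on zeta = +1;
#  * units: coordinates cm, conductivity S/m, potentials mV, time ms.

# local corner indices (1-based) of the six faces of a hexahedron, each
# ordered so the right-hand normal points out of the element
.hex_faces_local <- rbind(
  c(1, 4, 3, 2),  # zeta = -1
  c(5, 6, 7, 8),  # zeta = +1
  c(1, 5, 8, 4),  # xi   = -1
  c(2, 3, 7, 6),  # xi   = +1
  c(1, 2, 6, 5),  # eta  = -1
  c(4, 8, 7, 3)   # eta  = +1
)

#' Tissue conductivity table
#'
#' Builds the table of tissue types available to a volume-conductor mesh.
#' Conductivities must be strictly positive and names unique.
#'
#' @param name character vector of tissue labels.
#' @param conductivity numeric vector of conductivities in S/m, same length.
#' @return A `data.frame` of class `ecgi_tissues` with columns `name` and
#'   `conductivity`.
#' @examples
#' tissue_table(c("muscle", "lung"), c(0.2, 0.05))
#' @export
tissue_table <- function(name, conductivity) {
  name <- as.character(name)
  conductivity <- as.numeric(conductivity)
  if (length(name) != length(conductivity))
    stop("'name' and 'conductivity' must have the same length")
  if (anyDuplicated(name))
    stop("tissue names must be unique")
  if (any(!is.finite(conductivity)) || any(conductivity <= 0))
    stop("conductivities must be finite and strictly positive")
  structure(data.frame(name = name, conductivity = conductivity,
                       stringsAsFactors = FALSE),
            class = c("ecgi_tissues", "data.frame"))
}

#' Effective conductivity of a mixed-tissue element
#'
#' The conductivity of an element containing several tissues is the
#' volume-fraction weighted mean of the tissue conductivities,
#' \eqn{\sigma_e = \sum_n f_n \sigma_n} with \eqn{f_n = V_n / V_e}.
#'
#' @param fractions named numeric vector of volume fractions (dimensionless,
#'   summing to 1).
#' @param tissues an [tissue_table()] object.
#' @param tol tolerance on the fraction sum.
#' @return Effective conductivity in S/m.
#' @examples
#' ts <- tissue_table(c("lung", "muscle"), c(0.05, 0.2))
#' effective_conductivity(c(lung = 0.5, muscle = 0.5), ts)
#' @export
effective_conductivity <- function(fractions, tissues, tol = 1e-9) {
  if (is.null(names(fractions)) || any(!nzchar(names(fractions))))
    stop("'fractions' must be a named vector of tissue fractions")
  unknown <- setdiff(names(fractions), tissues$name)
  if (length(unknown))
    stop("unknown tissue label(s): ", paste(unknown, collapse = ", "))
  if (any(fractions < -tol))
    stop("tissue fractions must be non-negative")
  if (abs(sum(fractions) - 1) > max(tol, 1e-9))
    stop("tissue fractions must sum to 1 (got ", format(sum(fractions)), ")")
  sigma <- tissues$conductivity[match(names(fractions), tissues$name)]
  sum(fractions * sigma)
}

# signed area vector of a (possibly warped) quadrilateral, as the sum of its
# two corner triangles; |result| is the area used for flat faces
.quad_area_vector <- function(p) {
  v1 <- p[2, ] - p[1, ]; v2 <- p[3, ] - p[1, ]; v3 <- p[4, ] - p[1, ]
  0.5 * (.cross3(v1, v2) + .cross3(v2, v3))
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# all 6 faces of all elements as a (6E) x 4 matrix of global node ids,
# rows grouped per element in .hex_faces_local order
.element_faces <- function(elements) {
  E <- nrow(elements)
  out <- matrix(0L, 6L * E, 4L)
  for (f in 1:6)
    out[(seq_len(E) - 1L) * 6L + f, ] <-
      elements[, .hex_faces_local[f, ], drop = FALSE]
  attr(out, "owner") <- rep(seq_len(E), each = 6L)
  attr(out, "local_face") <- rep(1:6, times = E)
  out
}

# canonical key of a face: sorted node ids
.face_key <- function(fmat) {
  s <- apply(fmat, 1L, function(r) paste(sort.int(r), collapse = "_"))
  s
}

.build_face_set <- function(face_nodes, owner, nodes, centroids, kind) {
  nf <- nrow(face_nodes)
  area <- numeric(nf)
  avec <- matrix(0, nf, 3)
  for (i in seq_len(nf)) {
    p <- nodes[face_nodes[i, ], , drop = FALSE]
    a <- .quad_area_vector(p)
    # orient outward from the owner element
    outward <- colMeans(p) - centroids[owner[i], ]
    if (sum(a * outward) < 0) {
      face_nodes[i, ] <- face_nodes[i, c(1, 4, 3, 2)]
      a <- -a
    }
    avec[i, ] <- a
    area[i] <- sqrt(sum(a^2))
  }
  list(nodes = face_nodes, owner = owner, area = area,
       area_vector = avec, kind = kind)
}

#' Construct a hexahedral volume-conductor mesh
#'
#' Validates the inputs, computes per-element effective conductivities from
#' the tissue fractions, and extracts the outer and epicardial surfaces.
#'
#' @param nodes numeric `N x 3` matrix of node coordinates in cm.
#' @param elements integer `E x 8` matrix of 1-based node ids in standard
#'   trilinear corner order.
#' @param tissues a [tissue_table()].
#' @param fractions numeric `E x n_tissue` matrix of volume fractions, with
#'   column names matching the tissue table; each row sums to 1.
#' @param heart logical vector of length `E` flagging heart elements.
#' @param surface_grid optional data frame mapping lateral outer-surface
#'   nodes to a structured `(level, sector)` index grid (used by the pyramid
#'   interpolation); columns `node`, `level`, `sector`, plus attributes
#'   `n_sectors` and `wrap`.
#' @return An object of class `ecgi_mesh`: a list with the validated inputs
#'   plus `sigma` (per-element effective conductivity, S/m), `outer_faces`,
#'   `epicardial_faces` (each a list of `nodes`, `owner`, `area`,
#'   `area_vector`, `kind`) and `on_outer_surface` node flags.
#' @export
ecgi_mesh <- function(nodes, elements, tissues, fractions, heart,
                      surface_grid = NULL) {
  nodes <- as.matrix(nodes); storage.mode(nodes) <- "double"
  elements <- as.matrix(elements); storage.mode(elements) <- "integer"
  if (ncol(nodes) != 3) stop("'nodes' must be an N x 3 matrix")
  if (any(!is.finite(nodes))) stop("node coordinates must be finite")
  if (ncol(elements) != 8) stop("'elements' must be an E x 8 matrix")
  N <- nrow(nodes); E <- nrow(elements)
  if (any(elements < 1L) || any(elements > N))
    stop("element node ids out of range")
  if (any(apply(elements, 1, anyDuplicated) > 0))
    stop("each element must reference 8 distinct nodes")
  if (!inherits(tissues, "ecgi_tissues")) stop("'tissues' must be a tissue_table()")
  fractions <- as.matrix(fractions)
  if (nrow(fractions) != E) stop("'fractions' must have one row per element")
  if (is.null(colnames(fractions)) ||
      !all(colnames(fractions) %in% tissues$name))
    stop("fraction columns must be named after tissues")
  if (any(fractions < -1e-9)) stop("tissue fractions must be non-negative")
  bad <- abs(rowSums(fractions) - 1) > 1e-9
  if (any(bad))
    stop("tissue fractions must sum to 1 for every element (first bad: ",
         which(bad)[1], ")")
  heart <- as.logical(heart)
  if (length(heart) != E) stop("'heart' must flag every element")

  sigma <- as.numeric(fractions %*%
                        tissues$conductivity[match(colnames(fractions), tissues$name)])

  centroids <- t(vapply(seq_len(E),
                        function(e) colMeans(nodes[elements[e, ], , drop = FALSE]),
                        numeric(3)))

  mesh <- structure(list(
    nodes = nodes, elements = elements, tissues = tissues,
    fractions = fractions, sigma = sigma, heart = heart,
    centroids = centroids, surface_grid = surface_grid),
    class = "ecgi_mesh")

  mesh$outer_faces <- extract_outer_surface(mesh)
  mesh$on_outer_surface <- rep(FALSE, N)
  mesh$on_outer_surface[unique(as.vector(mesh$outer_faces$nodes))] <- TRUE
  mesh$epicardial_faces <- if (any(heart)) extract_epicardial_surface(mesh) else NULL
  mesh
}

#' @export
print.ecgi_mesh <- function(x, ...) {
  cat("Hexahedral volume-conductor mesh\n")
  cat(sprintf("  nodes: %d (%d on outer surface)\n",
              nrow(x$nodes), sum(x$on_outer_surface)))
  cat(sprintf("  elements: %d (%d heart)\n", nrow(x$elements), sum(x$heart)))
  cat(sprintf("  tissues: %s\n",
              paste(sprintf("%s=%.3g S/m", x$tissues$name, x$tissues$conductivity),
                    collapse = ", ")))
  cat(sprintf("  outer faces: %d, epicardial faces: %d\n",
              nrow(x$outer_faces$nodes),
              if (is.null(x$epicardial_faces)) 0L else nrow(x$epicardial_faces$nodes)))
  invisible(x)
}

#' Extract the outer (boundary) surface of a mesh
#'
#' Returns exactly the element faces referenced by a single element, each
#' oriented with outward normal.  Faces shared by more than two elements
#' indicate a non-manifold mesh and raise an error.
#'
#' @param mesh an [ecgi_mesh()] (or a partially built one with `nodes`,
#'   `elements`, `centroids`).
#' @return Face-set list: `nodes` (`F x 4` node ids), `owner` (element id),
#'   `area` (cm^2), `area_vector`, `kind = "outer"`.
#' @export
extract_outer_surface <- function(mesh) {
  fac <- .element_faces(mesh$elements)
  key <- .face_key(fac)
  cnt <- table(key)
  if (any(cnt > 2))
    stop("non-manifold mesh: a face is shared by more than 2 elements")
  single <- names(cnt)[cnt == 1]
  sel <- which(key %in% single)
  .build_face_set(fac[sel, , drop = FALSE], attr(fac, "owner")[sel],
                  mesh$nodes, mesh$centroids, "outer")
}

#' Extract the epicardial surface (heart boundary) of a mesh
#'
#' Epicardial faces are element faces separating a heart element from a
#' non-heart element, or lying on the boundary of the heart block.  Each
#' face is owned by its heart element and oriented outward from the heart.
#'
#' @param mesh an [ecgi_mesh()] with at least one heart element.
#' @return Face-set list as in [extract_outer_surface()], `kind = "epicardial"`.
#' @export
extract_epicardial_surface <- function(mesh) {
  if (!any(mesh$heart)) stop("mesh has no heart elements")
  he <- which(mesh$heart)
  fac <- .element_faces(mesh$elements)
  owner <- attr(fac, "owner")
  key <- .face_key(fac)
  heart_face <- owner %in% he
  # a heart face is epicardial iff its key is not shared with another heart
  # element (i.e. the face is either on the mesh boundary or its twin is
  # owned by a non-heart element)
  heart_keys <- key[heart_face]
  dup_within_heart <- heart_keys %in% heart_keys[duplicated(heart_keys)]
  sel <- which(heart_face)[!dup_within_heart]
  .build_face_set(fac[sel, , drop = FALSE], owner[sel],
                  mesh$nodes, mesh$centroids, "epicardial")
}

#' Node ids on the epicardial surface
#'
#' @param mesh an [ecgi_mesh()].
#' @return Sorted integer vector of epicardial node ids.
#' @export
epicardial_nodes <- function(mesh) {
  if (is.null(mesh$epicardial_faces)) stop("mesh has no epicardial surface")
  sort(unique(as.vector(mesh$epicardial_faces$nodes)))
}

# minimum Jacobian determinant of an element over the 2x2x2 Gauss points
.hex_min_jacobian <- function(coords) {
  g <- 1 / sqrt(3)
  dets <- numeric(8)
  i <- 0
  for (zc in c(-g, g)) for (yc in c(-g, g)) for (xc in c(-g, g)) {
    i <- i + 1
    dN <- hex_shape(xc, yc, zc)$gradients
    J <- t(dN) %*% coords
    dets[i] <- det(J)
  }
  min(dets)
}

#' Diagnostic report for a volume-conductor mesh
#'
#' Pure report (never raises): checks element Jacobian positivity at the
#' 2x2x2 Gauss points, repeated node ids inside elements, tissue fraction
#' sums, outer-surface closure (the signed face area vectors of a closed
#' surface sum to zero), and epicardial face ownership.
#'
#' @param mesh an [ecgi_mesh()] (or compatible list).
#' @return A list of class `ecgi_mesh_report` with per-check results and an
#'   overall `ok` flag.
#' @export
validate_mesh <- function(mesh) {
  E <- nrow(mesh$elements)
  dup <- vapply(seq_len(E),
                function(e) anyDuplicated(mesh$elements[e, ]) > 0, logical(1))
  minJ <- vapply(seq_len(E), function(e)
    .hex_min_jacobian(mesh$nodes[mesh$elements[e, ], , drop = FALSE]),
    numeric(1))
  frac_err <- if (!is.null(mesh$fractions))
    max(abs(rowSums(mesh$fractions) - 1)) else NA_real_
  closure <- if (!is.null(mesh$outer_faces)) {
    v <- colSums(mesh$outer_faces$area_vector)
    sqrt(sum(v^2)) / max(sum(mesh$outer_faces$area), .Machine$double.eps)
  } else NA_real_
  epi_ok <- if (!is.null(mesh$epicardial_faces))
    all(mesh$heart[mesh$epicardial_faces$owner]) else NA
  rep <- list(
    n_elements = E,
    repeated_node_elements = which(dup),
    min_jacobian = minJ,
    negative_jacobian_elements = which(minJ <= 0),
    fraction_sum_error = frac_err,
    outer_closure_rel = closure,
    epicardial_owners_are_heart = epi_ok,
    ok = !any(dup) && all(minJ > 0) &&
      (is.na(frac_err) || frac_err < 1e-9) &&
      (is.na(closure) || closure < 1e-9) &&
      (is.na(epi_ok) || isTRUE(epi_ok))
  )
  class(rep) <- "ecgi_mesh_report"
  rep
}

#' @export
print.ecgi_mesh_report <- function(x, ...) {
  cat("Mesh diagnostics:",
      if (x$ok) "all checks pass" else "PROBLEMS FOUND", "\n")
  cat(sprintf("  elements: %d, min Jacobian: %.3g\n",
              x$n_elements, min(x$min_jacobian)))
  if (length(x$repeated_node_elements))
    cat("  elements with repeated nodes:",
        paste(x$repeated_node_elements, collapse = ", "), "\n")
  if (length(x$negative_jacobian_elements))
    cat("  elements with non-positive Jacobian:",
        paste(x$negative_jacobian_elements, collapse = ", "), "\n")
  cat(sprintf("  fraction sum error: %.3g, outer closure (rel): %.3g\n",
              x$fraction_sum_error, x$outer_closure_rel))
  invisible(x)
}
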