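# Trilinear hexahedral FEM assembly: conductivity (stiffness) matrix,
# lumped mass matrices for the discrete volume/surface inner products, and
# the equivalent admittance network of the surface.
#
# Element integrals use 2x2x2 Gauss quadrature (exact for trilinear shape
# functions on parallelepipeds, the standard choice for general hexahedra);
# face integrals use 2x2 Gauss.
#
# Unit convention: coordinates are cm and conductivities S/m.  The entries
# of sigma * integral(grad Ni . grad Nj) dV then carry S.cm/m; a single
# scale constant `unit_scale` (default 1e-2 m/cm) converts them to siemens.
# Only ratios and reconstructions are contractual downstream, so the scale
# affects no result, but the convention is fixed here once.

#' Trilinear hexahedral shape functions
#'
#' Evaluates the eight trilinear shape functions and their reference-space
#' gradients at a point of the reference element \eqn{[-1,1]^3}.
#'
#' @param xi,eta,zeta reference coordinates, each in `[-1, 1]`.
#' @return List with `values` (length 8, a partition of unity) and
#'   `gradients` (`8 x 3`, rows summing to zero componentwise).
#' @export
hex_shape <- function(xi, eta, zeta) {
  if (max(abs(c(xi, eta, zeta))) > 1 + 1e-12)
    stop("point outside the reference element")
  sx <- c(-1, 1, 1, -1, -1, 1, 1, -1)
  sy <- c(-1, -1, 1, 1, -1, -1, 1, 1)
  sz <- c(-1, -1, -1, -1, 1, 1, 1, 1)
  a <- 1 + sx * xi; b <- 1 + sy * eta; cc <- 1 + sz * zeta
  N <- a * b * cc / 8
  dN <- cbind(sx * b * cc, a * sy * cc, a * b * sz) / 8
  list(values = N, gradients = dN)
}

# 2x2x2 Gauss rule on [-1,1]^3: points and (unit) weights, with shape
# values/gradients precomputed once
.hex_gauss <- local({
  g <- 1 / sqrt(3)
  pts <- as.matrix(expand.grid(xi = c(-g, g), eta = c(-g, g), zeta = c(-g, g)))
  shp <- lapply(seq_len(8), function(i)
    hex_shape(pts[i, 1], pts[i, 2], pts[i, 3]))
  list(points = pts, shapes = shp)
})

#' Element conductivity (stiffness) matrix
#'
#' Computes \eqn{K_e = \sigma_e \int_e \nabla N_i \cdot \nabla N_j \, dV}
#' by 2x2x2 Gauss quadrature.  The result is symmetric, has zero row sums
#' (constants lie in the null space) and scales linearly with `sigma`.
#'
#' @param coords `8 x 3` matrix of corner coordinates (cm), trilinear order.
#' @param sigma effective element conductivity (S/m).
#' @return `8 x 8` element matrix (units S.cm/m before global scaling).
#' @export
element_stiffness <- function(coords, sigma = 1) {
  coords <- as.matrix(coords)
  Ke <- matrix(0, 8, 8)
  for (q in .hex_gauss$shapes) {
    J <- t(q$gradients) %*% coords          # J[a,b] = d x_b / d xi_a
    dJ <- det(J)
    if (dJ <= 0) stop("degenerate element: non-positive Jacobian")
    G <- q$gradients %*% t(solve(J))        # physical gradients, 8 x 3
    Ke <- Ke + tcrossprod(G) * dJ
  }
  sigma * Ke
}

#' Assemble the global conductivity matrix
#'
#' Scatter-adds the element matrices of [element_stiffness()] into a sparse
#' symmetric `N x N` matrix, the FEM discretization of
#' \eqn{\nabla\cdot(\sigma\nabla\,\cdot)} with natural (insulated) boundary
#' conditions.  The matrix is pure-Neumann singular: constants span its
#' null space (one constant per connected component); the singular mode is
#' kept and handled downstream.
#'
#' @param mesh an [ecgi_mesh()].
#' @param unit_scale scale constant applied to every entry (default `1e-2`,
#'   converting S.cm/m to S; see the unit note above).
#' @return A sparse symmetric [Matrix::dgCMatrix-class].
#' @export
assemble_stiffness <- function(mesh, unit_scale = 1e-2) {
  E <- nrow(mesh$elements)
  ii <- integer(64L * E); jj <- integer(64L * E); xx <- numeric(64L * E)
  pos <- 0L
  for (e in seq_len(E)) {
    en <- mesh$elements[e, ]
    Ke <- element_stiffness(mesh$nodes[en, , drop = FALSE], mesh$sigma[e])
    idx <- pos + 1:64
    ii[idx] <- rep(en, times = 8)
    jj[idx] <- rep(en, each = 8)
    xx[idx] <- as.vector(Ke)
    pos <- pos + 64L
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx * unit_scale,
                            dims = c(nrow(mesh$nodes), nrow(mesh$nodes)))
  (K + Matrix::t(K)) / 2
}

# lumped (2x2 Gauss row-sum) face weights and area of one quadrilateral
.quad_face_lumped <- function(p) {
  g <- 1 / sqrt(3)
  w <- numeric(4); area <- 0
  sx <- c(-1, 1, 1, -1); sy <- c(-1, -1, 1, 1)
  for (xc in c(-g, g)) for (yc in c(-g, g)) {
    N <- (1 + sx * xc) * (1 + sy * yc) / 4
    dNx <- cbind(sx * (1 + sy * yc), (1 + sx * xc) * sy) / 4
    tx <- t(dNx) %*% p                     # 2 x 3 tangent rows
    da <- sqrt(sum(.cross3(tx[1, ], tx[2, ])^2))
    w <- w + N * da
    area <- area + da
  }
  list(weights = w, area = area)
}

# consistent (bilinear) surface mass matrix of one quadrilateral, 2x2 Gauss
.quad_face_consistent <- function(p) {
  g <- 1 / sqrt(3)
  M <- matrix(0, 4, 4)
  sx <- c(-1, 1, 1, -1); sy <- c(-1, -1, 1, 1)
  for (xc in c(-g, g)) for (yc in c(-g, g)) {
    N <- (1 + sx * xc) * (1 + sy * yc) / 4
    dNx <- cbind(sx * (1 + sy * yc), (1 + sx * xc) * sy) / 4
    tx <- t(dNx) %*% p
    da <- sqrt(sum(.cross3(tx[1, ], tx[2, ])^2))
    M <- M + tcrossprod(N) * da
  }
  M
}

#' Lumped mass vector for a volume or surface inner product
#'
#' Realizes the discrete inner products \eqn{\int f g \, dV} and
#' \eqn{\int f g \, dS} with diagonal (row-sum lumped) mass matrices.
#' Lumping makes the nodal shape functions exactly orthogonal in the
#' discrete inner product, which is what makes the shape-function
#' orthogonality used by the epicardial projection exact rather than
#' approximate.
#'
#' @param mesh an [ecgi_mesh()].
#' @param domain `"volume"` (nodal volumes, cm^3), `"outer"` or
#'   `"epicardial"` (nodal areas of the face set, cm^2).
#' @return Numeric `N`-vector; zero at nodes not touched by the domain.
#'   Entries sum to the total volume / area of the domain.
#' @export
assemble_lumped_mass <- function(mesh,
                                 domain = c("volume", "outer", "epicardial")) {
  domain <- match.arg(domain)
  N <- nrow(mesh$nodes)
  m <- numeric(N)
  if (domain == "volume") {
    for (e in seq_len(nrow(mesh$elements))) {
      en <- mesh$elements[e, ]
      coords <- mesh$nodes[en, , drop = FALSE]
      for (q in .hex_gauss$shapes) {
        dJ <- det(t(q$gradients) %*% coords)
        m[en] <- m[en] + q$values * dJ
      }
    }
  } else {
    faces <- if (domain == "outer") mesh$outer_faces else mesh$epicardial_faces
    if (is.null(faces) || nrow(faces$nodes) == 0)
      stop("mesh has no ", domain, " face set")
    for (f in seq_len(nrow(faces$nodes))) {
      fn <- faces$nodes[f, ]
      lw <- .quad_face_lumped(mesh$nodes[fn, , drop = FALSE])
      m[fn] <- m[fn] + lw$weights
    }
  }
  m
}

# consistent surface mass matrix over a face set (sparse N x N)
.surface_consistent_mass <- function(mesh, faces) {
  nf <- nrow(faces$nodes)
  ii <- integer(16L * nf); jj <- integer(16L * nf); xx <- numeric(16L * nf)
  pos <- 0L
  for (f in seq_len(nf)) {
    fn <- faces$nodes[f, ]
    Mf <- .quad_face_consistent(mesh$nodes[fn, , drop = FALSE])
    idx <- pos + 1:16
    ii[idx] <- rep(fn, times = 4)
    jj[idx] <- rep(fn, each = 4)
    xx[idx] <- as.vector(Mf)
    pos <- pos + 16L
  }
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(nrow(mesh$nodes), nrow(mesh$nodes)))
  (M + Matrix::t(M)) / 2
}

#' Equivalent admittance network of a surface
#'
#' Every FEM element can be represented by an equivalent resistive network;
#' the branch between surface nodes `i != j` carries the admittance
#' `Y_ij = -K_ij` taken from the assembled conductivity matrix, together
#' with the Euclidean branch length.  Used by the surface current-source
#' estimator.  Note that general hexahedra can produce negative branch
#' admittances (positive off-diagonal stiffness entries); they are reported
#' as-is.
#'
#' @param mesh an [ecgi_mesh()].
#' @param K assembled conductivity matrix (computed if `NULL`).
#' @param surface `"outer"` or `"epicardial"`.
#' @return `data.frame` with columns `i`, `j` (`i < j`), `Y` (S) and
#'   `dL` (cm), one row per unique branch.
#' @export
admittance_network <- function(mesh, K = NULL, surface = "outer") {
  if (is.null(K)) K <- assemble_stiffness(mesh)
  faces <- if (surface == "outer") mesh$outer_faces else mesh$epicardial_faces
  surf_nodes <- sort(unique(as.vector(faces$nodes)))
  Ks <- K[surf_nodes, surf_nodes, drop = FALSE]
  Kt <- methods::as(methods::as(Ks, "generalMatrix"), "TsparseMatrix")
  sel <- Kt@i < Kt@j & Kt@x != 0
  i <- surf_nodes[Kt@i[sel] + 1L]
  j <- surf_nodes[Kt@j[sel] + 1L]
  dL <- sqrt(rowSums((mesh$nodes[i, , drop = FALSE] -
                        mesh$nodes[j, , drop = FALSE])^2))
  data.frame(i = i, j = j, Y = -Kt@x[sel], dL = dL)
}
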