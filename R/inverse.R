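# The direct inverse: expansion weights from the Huygens surface source
# (voltage or current form), volume potential reconstruction, and the
# epicardial projection.

#' Expansion weights from the surface voltage source
#'
#' The default path of the method: the interpolated surface potentials are
#' the Huygens voltage source, and the weight of retained mode `m` at each
#' time sample is the surface inner product
#' \eqn{w_m(t) = \sum_s [V_n]_{geom}(m, s) \, V_d(s, t)} — a single
#' matrix product per beat, because the geometric factors are computed
#' once per basis (see [geometric_factors()]).  Weights carry mV.cm^2;
#' the scale is documented rather than normalized away, and only ratios
#' and reconstructions are contractual.
#'
#' @param distribution an [pyramid_interpolate()] result (or any list with
#'   `nodes` and `values`).
#' @param geom_factors an outer-surface [geometric_factors()] object.
#' @param retained optional logical mask over modes; rows of the result
#'   outside the mask are zero.  Default: all modes of the factors.
#' @return `WeightSeries` matrix, `modes x T`.
#' @export
weights_from_voltage <- function(distribution, geom_factors, retained = NULL) {
  if (geom_factors$surface != "outer")
    stop("weight extraction needs outer-surface geometric factors")
  idx <- match(geom_factors$nodes, distribution$nodes)
  if (any(is.na(idx)))
    stop("surface distribution does not cover the geometric-factor nodes")
  w <- geom_factors$matrix %*% distribution$values[idx, , drop = FALSE]
  if (!is.null(retained)) w[!retained, ] <- 0
  w
}

#' Expansion weights from the surface current source
#'
#' The flagged alternative path: branch source strengths from
#' [surface_current_source()] are gathered onto the eigenvectors (each
#' branch contributes its strength times the mean of the eigenvector at
#' its two end nodes) and divided by the spectral shift,
#' \eqn{w_m = \langle I, \hat V_m\rangle_S / (\lambda - \lambda_m)}.
#' The standalone shift \eqn{\lambda} defaults to 0 (static problem);
#' a retained \eqn{\lambda_m} equal to the shift signals that the zero
#' mode was not excluded and raises an error.
#'
#' @param branch_sources matrix `n_branches x T` from
#'   [surface_current_source()].
#' @param network the matching [admittance_network()].
#' @param basis an `ecgi_basis`.
#' @param lambda_shift spectral shift (default 0).
#' @param retained optional logical mask over modes (default
#'   `basis$retained`).
#' @return `WeightSeries` matrix, `modes x T` (zero rows for non-retained
#'   modes).
#' @export
weights_from_current <- function(branch_sources, network, basis,
                                 lambda_shift = 0, retained = NULL) {
  if (is.null(retained)) retained <- basis$retained
  denom <- lambda_shift - basis$values
  if (any(retained & abs(denom) < basis$null_tol))
    stop("division by zero for a retained mode: ",
         "the lambda = lambda_shift mode must be excluded")
  Vm <- (basis$vectors[network$i, , drop = FALSE] +
           basis$vectors[network$j, , drop = FALSE]) / 2
  w <- t(Vm) %*% branch_sources / denom
  w[!retained, ] <- 0
  w
}

#' Volume potential from expansion weights
#'
#' Reconstructs the modal expansion
#' \eqn{V(x) = \sum_{m \in R} w_m \hat V_m(x)} at every mesh node.
#'
#' @param weights `WeightSeries` matrix (`modes x T`).
#' @param basis an `ecgi_basis` sharing the retained set.
#' @param retained optional logical mask (default `basis$retained`).
#' @param t time sample index (default all).
#' @return `N x T` matrix of node potentials (mV).
#' @export
volume_potential <- function(weights, basis, retained = NULL, t = NULL) {
  if (is.null(retained)) retained <- basis$retained
  if (!is.matrix(weights)) weights <- matrix(weights, ncol = 1)
  if (nrow(weights) != length(basis$values))
    stop("weights and basis must share the mode set")
  if (!is.null(t)) weights <- weights[, t, drop = FALSE]
  R <- which(retained)
  basis$vectors[, R, drop = FALSE] %*% weights[R, , drop = FALSE]
}

#' Epicardial projection of the volume potential
#'
#' Applies the equivalence principle a second time on the heart surface:
#' the epicardial voltage source is expanded in the FEM shape functions of
#' the epicardial faces and its nodal values are extracted by
#' shape-function orthogonality,
#' \eqn{V_{epic,k} = \int_{S_{epic}} \sum_m w_m \hat V_m N_k^* dS / nf_k}
#' with \eqn{nf_k = \int N_k^2 dS} the normalization factor.  Under the
#' package's lumped surface inner product the shape functions are exactly
#' orthogonal and the projection reduces to the volume potential restricted
#' to the epicardial nodes (a documented consequence of lumping);
#' `method = "consistent"` keeps the full bilinear (Galerkin) products as
#' a cross-check.
#'
#' @param weights `WeightSeries` matrix.
#' @param basis an `ecgi_basis`.
#' @param mesh the mesh (must carry an epicardial surface).
#' @param method `"lumped"` (default) or `"consistent"`.
#' @param retained optional logical mask (default `basis$retained`).
#' @return Object of class `ecgi_epi`: list with `nodes` (epicardial node
#'   ids) and `values` (`E_n x T`, mV).
#' @export
epicardial_projection <- function(weights, basis, mesh,
                                  method = c("lumped", "consistent"),
                                  retained = NULL) {
  method <- match.arg(method)
  if (is.null(mesh$epicardial_faces)) stop("mesh has no epicardial surface")
  enodes <- epicardial_nodes(mesh)
  V <- volume_potential(weights, basis, retained = retained)
  if (method == "lumped") {
    nf <- assemble_lumped_mass(mesh, "epicardial")[enodes]
    if (any(nf <= 0)) stop("epicardial node with zero surface measure")
    vals <- V[enodes, , drop = FALSE]
  } else {
    Mc <- .surface_consistent_mass(mesh, mesh$epicardial_faces)
    Mce <- Mc[enodes, enodes, drop = FALSE]
    rhs <- Mce %*% V[enodes, , drop = FALSE]
    vals <- as.matrix(Matrix::solve(Mce, rhs))
  }
  structure(list(nodes = enodes, values = as.matrix(vals)),
            class = "ecgi_epi")
}

#' @export
print.ecgi_epi <- function(x, ...) {
  cat(sprintf("Epicardial solution: %d nodes x %d samples, range [%.3g, %.3g] mV\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}
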