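# Eigen-decomposition of the conductivity operator, mode sorting, energy
# truncation, conditioning diagnostics and the precomputed geometric
# surface factors of the weight extraction.

#' Generalized eigenpairs of the conductivity operator
#'
#' Solves \eqn{K \hat V_n = \lambda_n M \hat V_n} for the smallest
#' `k_modes` eigenvalues, with `M` the diagonal (lumped) volume mass, so
#' that the eigenvectors are M-orthonormal
#' (\eqn{\hat V^T M \hat V = I}).  The plain eigenanalysis of `K` alone is
#' recovered by passing `M = rep(1, N)`.
#'
#' With the diagonal mass the problem reduces to the standard symmetric
#' problem for \eqn{A = M^{-1/2} K M^{-1/2}}.  For small problems (or
#' `method = "dense"`) a full dense eigensolve is used; otherwise the
#' smallest modes are obtained by shift-invert Lanczos (ARPACK) with a
#' sparse Cholesky factorization of \eqn{A + \tau I}.
#'
#' @param K sparse symmetric conductivity matrix (see
#'   [assemble_stiffness()]).
#' @param M diagonal mass as a positive numeric `N`-vector (see
#'   [assemble_lumped_mass()]), or `NULL` for the identity.
#' @param k_modes number of smallest modes to compute (default: all).
#' @param method `"auto"` (dense when `k_modes` is close to `N` or `N` is
#'   small, ARPACK otherwise), `"dense"`, or `"arpack"`.
#' @return Object of class `ecgi_basis`: list with `values` (ascending
#'   eigenvalues), `vectors` (`N x k`, M-orthonormal), `mass` (the `M`
#'   vector), `retained` (logical, initialized to all `TRUE`),
#'   `null_modes` (indices of numerically zero eigenvalues) and
#'   `energy_fraction` (`NA` until [truncate_by_energy()] is applied).
#' @export
solve_eigenpairs <- function(K, M = NULL, k_modes = NULL,
                             method = c("auto", "dense", "arpack")) {
  method <- match.arg(method)
  N <- nrow(K)
  if (is.null(M)) M <- rep(1, N)
  if (length(M) != N || any(M <= 0))
    stop("'M' must be a positive N-vector")
  if (is.null(k_modes)) k_modes <- N
  k_modes <- min(k_modes, N)
  s <- 1 / sqrt(M)
  A <- Matrix::forceSymmetric(Matrix::Diagonal(N, s) %*% K %*% Matrix::Diagonal(N, s))
  if (method == "auto")
    method <- if (N <= 600 || k_modes > N - 2 || k_modes > N / 3) "dense" else "arpack"

  if (method == "dense") {
    ed <- eigen(as.matrix(A), symmetric = TRUE)
    ord <- seq(N, N - k_modes + 1)          # eigen() returns descending
    values <- ed$values[ord]
    phi <- ed$vectors[, ord, drop = FALSE]
  } else {
    scale0 <- mean(Matrix::diag(A))
    tau <- 1e-3 * scale0
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(A + Matrix::Diagonal(N, tau)),
                           LDL = FALSE, perm = TRUE)
    op <- function(x, extra) as.numeric(Matrix::solve(ch, x, system = "A"))
    ncv <- min(N, max(2L * k_modes + 1L, 20L))
    r <- igraph::arpack(op, sym = TRUE,
                        options = list(n = N, nev = k_modes, ncv = ncv,
                                       which = "LM", maxiter = 10000))
    values <- 1 / r$values - tau
    ord <- order(values)
    values <- values[ord]
    phi <- r$vectors[, ord, drop = FALSE]
    # Lanczos returns l2-orthonormal vectors up to solver tolerance;
    # tighten with one Gram-Schmidt pass
    phi <- qr.Q(qr(phi))
  }
  vectors <- phi * s                        # recycles s down columns
  # fix an arbitrary sign convention: largest-magnitude entry positive
  for (m in seq_len(ncol(vectors))) {
    p <- which.max(abs(vectors[, m]))
    if (vectors[p, m] < 0) vectors[, m] <- -vectors[, m]
  }
  null_tol <- max(abs(values)) * 1e-9 + .Machine$double.eps
  structure(list(values = values, vectors = vectors, mass = M,
                 retained = rep(TRUE, length(values)),
                 null_modes = which(abs(values) <= null_tol),
                 null_tol = null_tol,
                 energy_fraction = NA_real_),
            class = "ecgi_basis")
}

#' @export
print.ecgi_basis <- function(x, ...) {
  cat(sprintf("Eigenbasis: %d modes on %d nodes, lambda in [%.4g, %.4g]\n",
              length(x$values), nrow(x$vectors),
              min(x$values), max(x$values)))
  cat(sprintf("  retained: %d (energy fraction: %s), null modes: %d\n",
              sum(x$retained),
              if (is.na(x$energy_fraction)) "not truncated"
              else format(x$energy_fraction),
              length(x$null_modes)))
  invisible(x)
}

#' Energy-based spectral truncation
#'
#' The squared expansion weights are the modal powers (Parseval), so the
#' cumulative squared-weight curve identifies modes that carry essentially
#' no energy.  Truncation discards modes from the small-eigenvalue end
#' only — the end where numerically inaccurate near-zero modes live — as
#' long as the retained cumulative power stays at or above `fraction` of
#' the total.  The first small-eigenvalue mode whose removal would drop
#' the retained power below the threshold stops the scan.
#'
#' @param basis an [solve_eigenpairs()] basis.
#' @param weights a `WeightSeries` matrix (`modes x time`, as returned by
#'   [weights_from_voltage()]) computed over all modes of the basis, or a
#'   per-mode numeric vector of weights.
#' @param fraction retained energy fraction, in `(0, 1]` (default 0.999).
#' @param drop_null if `TRUE`, numerically zero eigenvalues (the constant
#'   mode of a connected insulated mesh) are always discarded, the usual
#'   reference convention; if `FALSE` they take part in the energy scan
#'   like any other small mode.
#' @return The basis with an updated `retained` mask, `energy_fraction`,
#'   and a `truncation` record (total power, discarded power, discarded
#'   mode indices).
#' @export
truncate_by_energy <- function(basis, weights, fraction = 0.999,
                               drop_null = TRUE) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("'fraction' must lie in (0, 1]")
  w <- if (is.matrix(weights)) weights else matrix(weights, ncol = 1)
  if (nrow(w) != length(basis$values))
    stop("weights must cover all modes of the basis")
  power <- rowSums(w^2)
  retained <- rep(TRUE, length(power))
  if (drop_null && length(basis$null_modes)) {
    # the constant mode goes by the reference convention, not by the
    # energy rule, so its power does not count against the budget
    retained[basis$null_modes] <- FALSE
    power[basis$null_modes] <- 0
  }
  discarded_power <- 0
  total <- sum(power)
  budget <- (1 - fraction) * total
  for (m in seq_along(power)) {            # ascending-eigenvalue order
    if (!retained[m]) next
    if (discarded_power + power[m] <= budget) {
      retained[m] <- FALSE
      discarded_power <- discarded_power + power[m]
    } else break
  }
  basis$retained <- retained
  basis$energy_fraction <- fraction
  basis$truncation <- list(total_power = total,
                           discarded_power = discarded_power,
                           discarded = which(!retained))
  basis
}

#' Condition number of the retained spectrum
#'
#' Ratio of the extreme retained eigenvalues,
#' \eqn{\max_R \lambda / \min_R \lambda}; it controls the numerical
#' stability of the modal expansion and is the paper-style diagnostic of
#' how much spectral truncation improves conditioning.  Retained
#' numerically-zero eigenvalues are an error (the reference convention
#' must remove the constant mode first).
#'
#' @param basis an `ecgi_basis`.
#' @param retained optional logical/integer mask overriding
#'   `basis$retained`.
#' @return Dimensionless ratio `>= 1`.
#' @export
condition_number <- function(basis, retained = NULL) {
  idx <- if (is.null(retained)) which(basis$retained)
  else if (is.logical(retained)) which(retained) else as.integer(retained)
  if (!length(idx)) stop("no retained modes")
  lam <- basis$values[idx]
  if (any(abs(lam) <= basis$null_tol))
    stop("retained spectrum contains a numerically zero eigenvalue")
  max(lam) / min(lam)
}

#' Geometric surface factors of the weight extraction
#'
#' The weight integral \eqn{w_m = \int_S V_d \hat V_m^* \, dS} factors
#' into a time-invariant geometric part — the surface integrals of the
#' eigenvectors — contracted with the time-varying surface potentials.
#' This function precomputes the geometric part once per basis:
#' with the default nodal lumping,
#' \eqn{[V_n]_{geom}(m, s) = \hat V_m(s)\, a_s} for surface node `s` with
#' lumped area `a_s` (the potential is treated as constant per
#' quadrilateral, which is what reduces the integral to nodal areas);
#' with `quadrature = "gauss"` the full bilinear product is integrated by
#' 2x2 Gauss per face, i.e. the factors become
#' \eqn{\hat V^T M_S^{cons}} with the consistent surface mass — the
#' slower alternative kept for cross-checks.
#'
#' @param basis an `ecgi_basis`.
#' @param mesh the [ecgi_mesh()] the basis was computed on.
#' @param surface `"outer"` or `"epicardial"`.
#' @param quadrature `"lumped"` (default) or `"gauss"`.
#' @param surface_mass optional precomputed lumped surface mass vector
#'   (see [assemble_lumped_mass()]); ignored for `"gauss"`.
#' @return Object of class `ecgi_geom`: list with `matrix`
#'   (`modes x n_surface_nodes`), `nodes` (surface node ids; factors are
#'   zero at all other nodes) and `surface`.
#' @export
geometric_factors <- function(basis, mesh,
                              surface = c("outer", "epicardial"),
                              quadrature = c("lumped", "gauss"),
                              surface_mass = NULL) {
  surface <- match.arg(surface)
  quadrature <- match.arg(quadrature)
  faces <- if (surface == "outer") mesh$outer_faces else mesh$epicardial_faces
  if (is.null(faces) || nrow(faces$nodes) == 0)
    stop("mesh has no ", surface, " face set")
  snodes <- sort(unique(as.vector(faces$nodes)))
  if (quadrature == "lumped") {
    if (is.null(surface_mass))
      surface_mass <- assemble_lumped_mass(mesh, surface)
    G <- t(basis$vectors[snodes, , drop = FALSE] * surface_mass[snodes])
  } else {
    Mc <- .surface_consistent_mass(mesh, faces)
    G <- as.matrix(Matrix::t(Mc[snodes, snodes, drop = FALSE] %*%
                               basis$vectors[snodes, , drop = FALSE]))
  }
  structure(list(matrix = G, nodes = snodes, surface = surface,
                 quadrature = quadrature),
            class = "ecgi_geom")
}
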