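# Forward problem (epicardial potentials -> body-surface potentials) and
# the self-validation metrics of the method.

#' Forward operator with epicardial Dirichlet data
#'
#' Factorizes the reduced conductivity system once for a fixed epicardial
#' node set so that many time samples (and repeated experiments) reuse the
#' factorization.  The forward convention is the standard ECGI one:
#' Dirichlet values on the epicardial nodes, natural (insulated) Neumann
#' condition on the torso surface; the Dirichlet block removes the
#' constant null space, so the solution is unique.
#'
#' @param mesh an [ecgi_mesh()].
#' @param K assembled conductivity matrix (computed if `NULL`).
#' @param dirichlet_nodes node ids carrying Dirichlet data (default: the
#'   epicardial surface nodes).
#' @return A function `f(values)` mapping a `length(dirichlet_nodes) x T`
#'   matrix to the full `N x T` solution.
#' @export
forward_operator <- function(mesh, K = NULL, dirichlet_nodes = NULL) {
  if (is.null(K)) K <- assemble_stiffness(mesh)
  if (is.null(dirichlet_nodes)) dirichlet_nodes <- epicardial_nodes(mesh)
  dn <- as.integer(dirichlet_nodes)        # caller order = value row order
  if (anyDuplicated(dn)) stop("duplicated Dirichlet node")
  if (!length(dn)) stop("empty Dirichlet node set")
  N <- nrow(K)
  free <- setdiff(seq_len(N), dn)
  Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
  Kfd <- K[free, dn, drop = FALSE]
  ch <- tryCatch(Matrix::Cholesky(Kff, LDL = FALSE, perm = TRUE),
                 error = function(e)
                   stop("singular reduced system: free region not ",
                        "anchored by the Dirichlet set (", conditionMessage(e), ")"))
  function(values) {
    values <- as.matrix(values)
    if (nrow(values) != length(dn))
      stop("Dirichlet data must have one row per Dirichlet node")
    u <- matrix(0, N, ncol(values))
    u[dn, ] <- values
    u[free, ] <- as.matrix(Matrix::solve(ch, -Kfd %*% values, system = "A"))
    u
  }
}

#' Solve the forward problem for given epicardial potentials
#'
#' @param mesh an [ecgi_mesh()].
#' @param K assembled conductivity matrix (computed if `NULL`).
#' @param epi an `ecgi_epi` (from [epicardial_projection()] or
#'   [simulate_epicardial_activation()]), or a matrix whose rows follow
#'   `dirichlet_nodes`.
#' @param dirichlet_nodes node ids for a plain-matrix `epi`.
#' @return List of class `ecgi_forward` with `potentials` (`N x T`, the
#'   Dirichlet nodes carry their imposed values exactly) and
#'   `residual_norm` (relative residual of the free block).
#' @export
forward_solve <- function(mesh, K = NULL, epi, dirichlet_nodes = NULL) {
  if (is.null(K)) K <- assemble_stiffness(mesh)
  if (inherits(epi, "ecgi_epi")) {
    dirichlet_nodes <- epi$nodes
    values <- epi$values
  } else values <- as.matrix(epi)
  op <- forward_operator(mesh, K, dirichlet_nodes)
  u <- op(values)
  free <- setdiff(seq_len(nrow(K)), as.integer(dirichlet_nodes))
  res <- K[free, , drop = FALSE] %*% u
  rel <- sqrt(sum(res^2)) / max(sqrt(sum(u^2)), .Machine$double.eps)
  structure(list(potentials = u, residual_norm = rel,
                 dirichlet_nodes = as.integer(dirichlet_nodes)),
            class = "ecgi_forward")
}

#' Extract electrode traces from a forward solution
#'
#' @param forward an `ecgi_forward` (or a plain `N x T` matrix).
#' @param layout an [electrode_layout()].
#' @return `M x T` matrix of electrode potentials (a `RecordingSet`).
#' @export
electrode_potentials <- function(forward, layout) {
  u <- if (inherits(forward, "ecgi_forward")) forward$potentials else as.matrix(forward)
  if (any(layout$node > nrow(u))) stop("layout references a missing node")
  out <- u[layout$node, , drop = FALSE]
  rownames(out) <- layout$electrode
  out
}

#' Per-electrode correlation report
#'
#' The self-validation metric: Pearson correlation coefficient between the
#' simulated and measured trace of each electrode over the full beat, plus
#' the per-electrode RMS error and the arithmetic mean CC.  Electrodes
#' with a zero-variance trace have an undefined CC; they are reported as
#' `NA` and excluded from the mean with a warning.
#'
#' @param simulated,measured `M x T` matrices with matching shapes.
#' @return List of class `ecgi_validation` with `cc` (per electrode),
#'   `mean_cc`, `rms` (mV) and `n_excluded`.
#' @export
correlation_report <- function(simulated, measured) {
  simulated <- as.matrix(simulated); measured <- as.matrix(measured)
  if (!all(dim(simulated) == dim(measured)))
    stop("simulated and measured traces must have equal shapes")
  M <- nrow(simulated)
  cc <- rep(NA_real_, M)
  for (e in seq_len(M)) {
    if (stats::sd(simulated[e, ]) > 0 && stats::sd(measured[e, ]) > 0)
      cc[e] <- stats::cor(simulated[e, ], measured[e, ])
  }
  if (anyNA(cc))
    warning(sum(is.na(cc)), " electrode(s) with zero-variance trace ",
            "excluded from the mean CC")
  rms <- sqrt(rowMeans((simulated - measured)^2))
  structure(list(cc = cc, mean_cc = mean(cc, na.rm = TRUE), rms = rms,
                 n_excluded = sum(is.na(cc))),
            class = "ecgi_validation")
}

#' @export
print.ecgi_validation <- function(x, ...) {
  cat(sprintf("Self-validation over %d electrodes: mean CC = %.4f (min %.4f)\n",
              length(x$cc), x$mean_cc, min(x$cc, na.rm = TRUE)))
  cat(sprintf("  RMS error: median %.4g mV\n", stats::median(x$rms)))
  invisible(x)
}
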