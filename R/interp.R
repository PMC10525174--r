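# Mapping sparse electrode recordings onto the full outer surface:
# electrode-to-node association, pyramid-patch interpolation, continuous
# bilinear surface evaluation, and the optional surface current source.

#' Electrode layout from known node ids
#'
#' @param node_ids integer vector of outer-surface node ids, one per
#'   electrode (injective).
#' @param mesh an [ecgi_mesh()].
#' @param electrode optional electrode ids (default `1..M`).
#' @return `data.frame` of class `ecgi_layout` with columns `electrode`,
#'   `node`.
#' @export
electrode_layout <- function(node_ids, mesh, electrode = seq_along(node_ids)) {
  node_ids <- as.integer(node_ids)
  if (anyDuplicated(node_ids))
    stop("two electrodes map to the same node: ",
         paste(node_ids[duplicated(node_ids)], collapse = ", "))
  if (!all(mesh$on_outer_surface[node_ids]))
    stop("electrode node(s) not on the outer surface: ",
         paste(node_ids[!mesh$on_outer_surface[node_ids]], collapse = ", "))
  structure(data.frame(electrode = electrode, node = node_ids),
            class = c("ecgi_layout", "data.frame"))
}

#' Associate electrode positions with mesh surface nodes
#'
#' Each electrode is mapped to the nearest outer-surface node (Euclidean
#' distance); ties are broken by the lowest node id.  Two electrodes
#' mapping to the same node is an error (the layout must stay injective).
#'
#' @param positions numeric `M x 3` matrix of electrode coordinates (cm).
#' @param mesh an [ecgi_mesh()].
#' @param electrode optional electrode ids.
#' @return An [electrode_layout()] with an extra `distance` column (cm).
#' @export
map_electrodes_to_nodes <- function(positions, mesh,
                                    electrode = seq_len(nrow(positions))) {
  positions <- as.matrix(positions)
  if (any(!is.finite(positions))) stop("electrode positions must be finite")
  surf <- which(mesh$on_outer_surface)
  sc <- mesh$nodes[surf, , drop = FALSE]
  nearest <- integer(nrow(positions)); dist <- numeric(nrow(positions))
  for (i in seq_len(nrow(positions))) {
    d2 <- (sc[, 1] - positions[i, 1])^2 + (sc[, 2] - positions[i, 2])^2 +
      (sc[, 3] - positions[i, 3])^2
    k <- which(d2 <= min(d2) + 1e-24)       # ties -> lowest node id
    nearest[i] <- surf[k[1]]
    dist[i] <- sqrt(d2[k[1]])
  }
  lay <- electrode_layout(nearest, mesh, electrode)
  lay$distance <- dist
  lay
}

# barycentric coordinates of 2D point p in triangle (a, b, c); returns
# c(l1, l2, l3) or NULL when the triangle is degenerate
.bary2 <- function(p, a, b, c) {
  T <- cbind(b - a, c - a)
  dt <- T[1, 1] * T[2, 2] - T[1, 2] * T[2, 1]
  if (abs(dt) < 1e-14) return(NULL)
  uv <- solve(T, p - a)
  c(1 - uv[1] - uv[2], uv[1], uv[2])
}

# signed sector offset with wraparound
.sector_delta <- function(s, s0, n_sectors, wrap) {
  d <- s - s0
  if (wrap) d <- ((d + n_sectors / 2) %% n_sectors) - n_sectors / 2
  d
}

#' Pyramid-patch interpolation of electrode recordings
#'
#' Interpolates the per-electrode time series onto every outer-surface
#' node.  Each electrode is the apex of a pyramid patch spanning to its
#' neighbouring electrodes on the electrode lattice; each quadrant of the
#' patch is realized as two tetrahedral sub-elements split along a fixed
#' diagonal, so the surface in between is covered by the fan of lateral
#' triangles around the apex, on which the shape functions restrict to
#' linear barycentric interpolation between three electrodes.  Where
#' several electrode pyramids cover a node the
#' accumulated weights are renormalized to sum to one, so constants are
#' reproduced exactly and electrode nodes keep their recorded values
#' exactly.
#'
#' The electrode lattice lives on the structured `(level, sector)` index
#' grid stored in `mesh$surface_grid` (the synthetic torso provides it;
#' see [build_synthetic_torso()]).  Surface nodes off that grid — e.g. the
#' torso end caps — or outside every patch are filled by inverse-distance
#' weighting over the `idw_k` nearest electrodes, a documented fallback.
#'
#' @param recordings numeric `M x T` matrix of electrode potentials (mV),
#'   rows ordered as in `layout`.
#' @param layout an [electrode_layout()].
#' @param mesh an [ecgi_mesh()] with a `surface_grid`.
#' @param idw_k number of electrodes used by the fallback (default 3).
#' @return Object of class `ecgi_distribution`: list with `nodes` (outer
#'   surface node ids), `values` (`S_n x T`), the sparse interpolation
#'   `weights` (`S_n x M`), and `fallback_nodes` (ids filled by the IDW
#'   fallback).  Implicitly the distribution is zero off the outer
#'   surface (the Huygens restriction).
#' @export
pyramid_interpolate <- function(recordings, layout, mesh, idw_k = 3) {
  recordings <- as.matrix(recordings)
  if (nrow(recordings) != nrow(layout))
    stop("recordings must have one row per electrode")
  if (any(!is.finite(recordings))) stop("recordings must be finite")
  snodes <- which(mesh$on_outer_surface)
  Sn <- length(snodes); M <- nrow(layout)
  W <- matrix(0, Sn, M)
  covered <- rep(FALSE, Sn)
  grid <- mesh$surface_grid

  if (!is.null(grid)) {
    wrap <- isTRUE(attr(grid, "wrap"))
    n_sectors <- attr(grid, "n_sectors")
    gl <- grid$level[match(layout$node, grid$node)]
    gs <- grid$sector[match(layout$node, grid$node)]
    on_grid <- which(!is.na(gl))
    lev <- sort(unique(gl[on_grid]))
    sec <- sort(unique(gs[on_grid]))
    # electrode index on the (level, sector) lattice
    emat <- matrix(NA_integer_, length(lev), length(sec))
    for (e in on_grid)
      emat[match(gl[e], lev), match(gs[e], sec)] <- e
    nl <- length(lev); ns <- length(sec)
    node_lev <- grid$level[match(snodes, grid$node)]
    node_sec <- grid$sector[match(snodes, grid$node)]

    elect_at <- function(i, j) {            # lattice lookup with sector wrap
      if (i < 1 || i > nl) return(NA_integer_)
      if (wrap) j <- ((j - 1) %% ns) + 1 else if (j < 1 || j > ns) return(NA_integer_)
      emat[i, j]
    }
    sec_of <- function(j) sec[((j - 1) %% ns) + 1]

    for (q in seq_len(Sn)) {
      if (is.na(node_lev[q])) next
      l <- node_lev[q]; s <- node_sec[q]
      i <- findInterval(l, lev)
      if (i < 1 || l > lev[nl]) next
      # sector bracket (unwrapped index j such that sec[j] <= s < sec[j+1])
      j <- findInterval(s, sec)
      if (j < 1) j <- if (wrap) ns else next
      acc <- numeric(M); tot <- 0
      for (ai in unique(c(i, min(i + 1, nl)))) for (aj in c(j, j + 1)) {
        apex <- elect_at(ai, aj)
        if (is.na(apex)) next
        l0 <- gl[apex]; s0 <- gs[apex]
        p <- c(l - l0, .sector_delta(s, s0, n_sectors, wrap))
        # the fan of lateral triangles around this apex: consecutive pairs
        # of the eight lattice neighbours (the two tetrahedral sub-elements
        # of each pyramid quadrant, split along the fixed diagonal)
        nb <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1),
                   c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1))
        cid <- vapply(nb, function(d) elect_at(ai + d[1], aj + d[2]),
                      integer(1))
        cxy <- lapply(seq_len(8), function(k) {
          if (is.na(cid[k])) return(NULL)
          c(gl[cid[k]] - l0,
            .sector_delta(gs[cid[k]], s0, n_sectors, wrap))
        })
        for (k1 in seq_len(8)) {
          k2 <- k1 %% 8L + 1L
          if (is.na(cid[k1]) || is.na(cid[k2])) next
          bb <- .bary2(p, c(0, 0), cxy[[k1]], cxy[[k2]])
          if (is.null(bb) || any(bb < -1e-9)) next
          acc[apex] <- acc[apex] + bb[1]
          acc[cid[k1]] <- acc[cid[k1]] + bb[2]
          acc[cid[k2]] <- acc[cid[k2]] + bb[3]
          tot <- tot + sum(bb)
        }
      }
      if (tot > 1e-12) {
        W[q, ] <- acc / tot
        covered[q] <- TRUE
      }
    }
  }

  # exactness at electrode nodes regardless of patch geometry
  eidx <- match(layout$node, snodes)
  for (e in seq_len(M)) {
    W[eidx[e], ] <- 0
    W[eidx[e], e] <- 1
    covered[eidx[e]] <- TRUE
  }

  # inverse-distance fallback for uncovered nodes
  fallback <- which(!covered)
  if (length(fallback)) {
    epos <- mesh$nodes[layout$node, , drop = FALSE]
    for (q in fallback) {
      d <- sqrt(colSums((t(epos) - mesh$nodes[snodes[q], ])^2))
      k <- order(d)[seq_len(min(idw_k, M))]
      wq <- 1 / pmax(d[k], 1e-12)^2
      W[q, k] <- wq / sum(wq)
    }
  }

  structure(list(nodes = snodes,
                 values = W %*% recordings,
                 weights = Matrix::Matrix(W, sparse = TRUE),
                 fallback_nodes = snodes[fallback]),
            class = "ecgi_distribution")
}

#' @export
print.ecgi_distribution <- function(x, ...) {
  cat(sprintf("Surface potential distribution: %d surface nodes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  %d node(s) filled by the IDW fallback\n",
              length(x$fallback_nodes)))
  invisible(x)
}

#' Continuous surface potential inside a quadrilateral face
#'
#' Bilinear combination of the four nodal values of an outer-surface face
#' with the standard quad shape functions, evaluated at a reference point.
#'
#' @param distribution an [pyramid_interpolate()] result.
#' @param mesh the mesh.
#' @param face index into `mesh$outer_faces`.
#' @param xi,eta reference coordinates in `[-1, 1]`.
#' @param t time sample index (default all samples).
#' @return Potential(s) in mV.
#' @export
continuous_surface_potential <- function(distribution, mesh, face, xi, eta,
                                         t = NULL) {
  if (max(abs(c(xi, eta))) > 1 + 1e-12)
    stop("point outside the reference element")
  fn <- mesh$outer_faces$nodes[face, ]
  sx <- c(-1, 1, 1, -1); sy <- c(-1, -1, 1, 1)
  N <- (1 + sx * xi) * (1 + sy * eta) / 4
  vals <- distribution$values[match(fn, distribution$nodes), , drop = FALSE]
  out <- as.numeric(N %*% vals)
  if (is.null(t)) out else out[t]
}

#' Surface current source from the admittance network
#'
#' The paper-defined equivalent current on branch `(i, j)` is
#' \eqn{I = Y_{ij} (V_{dj} - V_{di}) / \Delta L_{ij}}; note the units
#' (admittance x voltage / length) are a paper-defined source strength
#' rather than a physical current, and are treated as such throughout.
#'
#' @param distribution an [pyramid_interpolate()] result.
#' @param network an [admittance_network()].
#' @param t time sample index (default all).
#' @return Matrix `n_branches x length(t)` of branch source strengths
#'   (antisymmetric under branch reversal).
#' @export
surface_current_source <- function(distribution, network, t = NULL) {
  if (any(network$dL <= 0)) stop("zero-length branch in the network")
  vi <- distribution$values[match(network$i, distribution$nodes), , drop = FALSE]
  vj <- distribution$values[match(network$j, distribution$nodes), , drop = FALSE]
  if (any(is.na(vi)) || any(is.na(vj)))
    stop("network references nodes outside the surface distribution")
  I <- (vj - vi) * (network$Y / network$dL)
  if (is.null(t)) I else I[, t, drop = FALSE]
}
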