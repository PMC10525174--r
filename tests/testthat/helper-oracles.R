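# Independent oracles, deliberately coded differently from the package
# kernels: high-order dense quadrature for element/global stiffness and
# per-face Gauss quadrature for the surface weight integrals.

# trilinear shape values/gradients at one point, written as products of 1D
# hat functions (independent of hex_shape's sign-vector formulation)
.oracle_shape <- function(xi, eta, zeta) {
  l <- function(s, x) (1 + s * x) / 2
  dl <- function(s) s / 2
  corners <- expand.grid(sx = c(-1, 1), sy = c(-1, 1), sz = c(-1, 1))
  # reorder to the trilinear corner convention
  ord <- c(1, 2, 4, 3, 5, 6, 8, 7)
  corners <- corners[ord, ]
  N <- numeric(8); dN <- matrix(0, 8, 3)
  for (k in 1:8) {
    sx <- corners$sx[k]; sy <- corners$sy[k]; sz <- corners$sz[k]
    N[k] <- l(sx, xi) * l(sy, eta) * l(sz, zeta)
    dN[k, ] <- c(dl(sx) * l(sy, eta) * l(sz, zeta),
                 l(sx, xi) * dl(sy) * l(sz, zeta),
                 l(sx, xi) * l(sy, eta) * dl(sz))
  }
  list(N = N, dN = dN)
}

# Gauss rules on [-1, 1]
.gauss1d <- list(`2` = list(x = c(-1, 1) / sqrt(3), w = c(1, 1)),
                 `3` = list(x = c(-sqrt(3 / 5), 0, sqrt(3 / 5)),
                            w = c(5, 8, 5) / 9))

# element stiffness by dense tensor Gauss quadrature; 3x3x3 is exact on
# parallelepipeds, n_gauss = 2 reproduces the method's own rule (the
# integrand is rational on warped hexahedra, so the rules differ there)
oracle_element_stiffness <- function(coords, sigma = 1, n_gauss = 3) {
  g1 <- .gauss1d[[as.character(n_gauss)]]
  Ke <- matrix(0, 8, 8)
  for (a in seq_len(n_gauss)) for (b in seq_len(n_gauss))
   for (cc in seq_len(n_gauss)) {
    sh <- .oracle_shape(g1$x[a], g1$x[b], g1$x[cc])
    J <- matrix(0, 3, 3)
    for (k in 1:8) J <- J + outer(sh$dN[k, ], coords[k, ])
    dJ <- det(J)
    G <- sh$dN %*% solve(t(J))             # physical gradients
    wgt <- g1$w[a] * g1$w[b] * g1$w[cc]
    for (i in 1:8) for (j in 1:8)
      Ke[i, j] <- Ke[i, j] + sigma * sum(G[i, ] * G[j, ]) * dJ * wgt
  }
  Ke
}

# dense global assembly from the oracle element matrices
oracle_assemble_stiffness <- function(mesh, unit_scale = 1e-2) {
  N <- nrow(mesh$nodes)
  K <- matrix(0, N, N)
  for (e in seq_len(nrow(mesh$elements))) {
    en <- mesh$elements[e, ]
    K[en, en] <- K[en, en] +
      oracle_element_stiffness(mesh$nodes[en, , drop = FALSE], mesh$sigma[e])
  }
  K * unit_scale
}

# surface weight integral int_S V_d Vhat_m dS by per-face 2x2 Gauss with
# both fields interpolated bilinearly (the Eq.-(18) quadrature oracle)
oracle_weights_gauss <- function(mesh, basis, distribution) {
  faces <- mesh$outer_faces
  k <- ncol(basis$vectors)
  Tn <- ncol(distribution$values)
  w <- matrix(0, k, Tn)
  g <- 1 / sqrt(3)
  sx <- c(-1, 1, 1, -1); sy <- c(-1, -1, 1, 1)
  for (f in seq_len(nrow(faces$nodes))) {
    fn <- faces$nodes[f, ]
    p <- mesh$nodes[fn, , drop = FALSE]
    vd <- distribution$values[match(fn, distribution$nodes), , drop = FALSE]
    vb <- basis$vectors[fn, , drop = FALSE]
    for (xc in c(-g, g)) for (yc in c(-g, g)) {
      N <- (1 + sx * xc) * (1 + sy * yc) / 4
      dN <- cbind(sx * (1 + sy * yc), (1 + sx * xc) * sy) / 4
      tg <- t(dN) %*% p
      da <- sqrt(sum((c(tg[1, 2] * tg[2, 3] - tg[1, 3] * tg[2, 2],
                        tg[1, 3] * tg[2, 1] - tg[1, 1] * tg[2, 3],
                        tg[1, 1] * tg[2, 2] - tg[1, 2] * tg[2, 1]))^2))
      w <- w + (t(vb) %*% N) %*% (N %*% vd) * da
    }
  }
  w
}

# two-chamber box mesh joined by a poorly conducting middle layer: its
# antisymmetric mode has a near-zero eigenvalue (the "numerical noise
# mode" scenario of the spectral truncation)
bridge_mesh <- function(nx = 7, ny = 2, nz = 2, bridge_sigma = 1e-5) {
  ts <- tissue_table(c("medium", "bridge"), c(1, bridge_sigma))
  E <- nx * ny * nz
  xi <- (seq_len(E) - 1) %% nx
  et <- ifelse(xi == (nx - 1) %/% 2, "bridge", "medium")
  build_box_mesh(nx, ny, nz, tissues = ts, element_tissue = et)
}

# flat slab with a structured surface grid on its lateral x-z "wall",
# used by the interpolation patch tests (wrap = FALSE)
flat_patch_mesh <- function(nx = 12, nz = 9, spacing = 1) {
  mesh <- build_box_mesh(nx, 1, nz, spacing = spacing)
  nid <- function(i, k) ((k * 2 + 0) * (nx + 1)) + i + 1   # j = 0 wall
  grid <- data.frame(node = as.integer(outer(0:nx, 0:nz, nid)),
                     level = rep(0:nz, each = nx + 1) + 1L,
                     sector = rep(0:nx, times = nz + 1) + 1L)
  attr(grid, "n_sectors") <- nx + 1L
  attr(grid, "wrap") <- FALSE
  mesh$surface_grid <- grid
  mesh
}

# small synthetic torso shared by several unit tests
small_torso <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- build_synthetic_torso(
        synth_config(n_levels = 7, n_sectors = 16, n_rings = 2,
                     heart_layers = 3:4))
    cache
  }
})

# access to the internal region-weight helper for the activation lag test
.region_weights_for_test <- function(mesh, region)
  directECGI:::.region_weights(mesh, region)

# short-beat activation parameters for fast pipeline tests
short_beat_params <- function(beat) {
  activation_params(data.frame(
    name = c("R", "T"), onset = c(round(beat * 0.1), round(beat * 0.5)),
    width = c(round(beat * 0.12), round(beat * 0.2)),
    amp = c(1.2, 0.4), region = c("rv", "ventricles")), beat_length = beat)
}
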