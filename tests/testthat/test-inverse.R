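# The weight extraction, volume reconstruction and epicardial projection.

.cube_setup <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      mesh <- build_box_mesh(3, 3, 3,
                             heart = replace(rep(FALSE, 27), 14, TRUE))
      K <- assemble_stiffness(mesh)
      M <- assemble_lumped_mass(mesh, "volume")
      cache <<- list(mesh = mesh, K = K, M = M,
                     basis = solve_eigenpairs(K, M))
    }
    cache
  }
})

test_that("voltage weights: zeros, orthonormal surface basis, Gauss oracle", {
  s <- .cube_setup()
  snodes <- which(s$mesh$on_outer_surface)
  geom <- geometric_factors(s$basis, s$mesh, "outer")
  # zero distribution -> zero weights
  w0 <- weights_from_voltage(list(nodes = snodes,
                                  values = matrix(0, length(snodes), 3)), geom)
  expect_true(all(w0 == 0))
  # a synthetic basis orthonormal under the surface mass gives w_m = delta_mk
  ms <- assemble_lumped_mass(s$mesh, "outer")[snodes]
  set.seed(17)
  Q <- qr.Q(qr(matrix(stats::rnorm(length(snodes) * 4), ncol = 4)))
  Vsurf <- Q / sqrt(ms)                     # columns orthonormal w.r.t. a_s
  fake <- s$basis
  fake$vectors <- matrix(0, nrow(s$mesh$nodes), 4)
  fake$vectors[snodes, ] <- Vsurf
  fake$values <- 1:4
  gf <- geometric_factors(fake, s$mesh, "outer")
  wk <- weights_from_voltage(list(nodes = snodes, values = Vsurf[, 2,
                                                                 drop = FALSE]),
                             gf)
  expect_equal(as.numeric(wk), c(0, 1, 0, 0), tolerance = 1e-10)
  # random distribution matches the per-face Gauss quadrature oracle
  vd <- matrix(stats::rnorm(length(snodes) * 2), ncol = 2)
  dist <- list(nodes = snodes, values = vd)
  w_pkg <- weights_from_voltage(dist,
                                geometric_factors(s$basis, s$mesh, "outer",
                                                  quadrature = "gauss"))
  expect_lt(max(abs(w_pkg - oracle_weights_gauss(s$mesh, s$basis, dist))),
            1e-6)
  # lumped and gauss factors agree exactly for face-constant distributions
  dconst <- list(nodes = snodes, values = matrix(2, length(snodes), 1))
  wl <- weights_from_voltage(dconst, geom)
  wg <- weights_from_voltage(dconst,
                             geometric_factors(s$basis, s$mesh, "outer",
                                               quadrature = "gauss"))
  expect_equal(as.numeric(wl), as.numeric(wg), tolerance = 1e-10)
})

test_that("current weights: zeros, linearity, dense-basis hand evaluation", {
  s <- .cube_setup()
  net <- admittance_network(s$mesh, s$K)
  nz <- !seq_along(s$basis$values) %in% s$basis$null_modes
  I0 <- matrix(0, nrow(net), 2)
  expect_true(all(weights_from_current(I0, net, s$basis,
                                       retained = nz) == 0))
  set.seed(23)
  I1 <- matrix(stats::rnorm(nrow(net) * 2), ncol = 2)
  w1 <- weights_from_current(I1, net, s$basis, retained = nz)
  # linearity: doubling every branch source doubles the weights
  expect_equal(weights_from_current(2 * I1, net, s$basis, retained = nz),
               2 * w1, tolerance = 1e-12)
  # hand evaluation of the formula on a single branch
  net1 <- net[5, , drop = FALSE]
  Ib <- matrix(1.3, 1, 1)
  wb <- weights_from_current(Ib, net1, s$basis, retained = nz)
  hand <- 1.3 * (s$basis$vectors[net1$i, ] + s$basis$vectors[net1$j, ]) / 2 /
    (0 - s$basis$values)
  hand[!nz] <- 0
  expect_equal(as.numeric(wb), hand, tolerance = 1e-10, ignore_attr = TRUE)
  # retained zero mode triggers the division-by-zero guard
  expect_error(weights_from_current(Ib, net1, s$basis,
                                    retained = rep(TRUE, length(nz))),
               "zero")
})

test_that("volume potential: unit weights, zeros, completeness round trip", {
  s <- .cube_setup()
  k <- length(s$basis$values)
  ek <- matrix(0, k, 1); ek[7] <- 1
  expect_equal(as.numeric(volume_potential(ek, s$basis,
                                           retained = rep(TRUE, k))),
               s$basis$vectors[, 7], tolerance = 1e-12)
  expect_true(all(volume_potential(matrix(0, k, 2), s$basis,
                                   retained = rep(TRUE, k)) == 0))
  # project a random field on the full basis and reconstruct it exactly
  set.seed(29)
  f <- stats::rnorm(nrow(s$mesh$nodes))
  w <- crossprod(s$basis$vectors, f * s$M)      # volume inner products
  recon <- volume_potential(w, s$basis, retained = rep(TRUE, k))
  expect_equal(as.numeric(recon), f, tolerance = 1e-8)
})

test_that("epicardial projection: constants, zeros, consistent-mass check", {
  s <- .cube_setup()
  k <- length(s$basis$values)
  all_ret <- rep(TRUE, k)
  # weights of the constant field c: the projection returns c at every node
  cfield <- rep(4.2, nrow(s$mesh$nodes))
  w <- crossprod(s$basis$vectors, cfield * s$M)
  epi <- epicardial_projection(w, s$basis, s$mesh, retained = all_ret)
  expect_equal(as.numeric(epi$values), rep(4.2, length(epi$nodes)),
               tolerance = 1e-8)
  expect_true(all(epicardial_projection(matrix(0, k, 2), s$basis, s$mesh,
                                        retained = all_ret)$values == 0))
  # lumped projection equals the nodal restriction of the volume potential
  set.seed(37)
  wr <- matrix(stats::rnorm(k * 2), k, 2)
  epi_l <- epicardial_projection(wr, s$basis, s$mesh, retained = all_ret)
  V <- volume_potential(wr, s$basis, retained = all_ret)
  expect_equal(epi_l$values, V[epi_l$nodes, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  # consistent-mass Galerkin projection stays within 5% relative
  epi_c <- epicardial_projection(wr, s$basis, s$mesh, method = "consistent",
                                 retained = all_ret)
  rel <- norm(epi_c$values - epi_l$values, "F") / norm(epi_l$values, "F")
  expect_lt(rel, 0.05)
})

test_that("the map from recordings to epicardial sources is linear", {
  mesh <- small_torso()
  K <- assemble_stiffness(mesh)
  M <- assemble_lumped_mass(mesh, "volume")
  basis <- solve_eigenpairs(K, M, k_modes = 60)
  lay <- synthetic_electrode_layout(mesh)
  geom <- geometric_factors(basis, mesh, "outer")
  invert <- function(rec) {
    d <- pyramid_interpolate(rec, lay, mesh)
    w <- weights_from_voltage(d, geom)
    epicardial_projection(w, basis, mesh,
                          retained = rep(TRUE, 60))$values
  }
  set.seed(41)
  r1 <- matrix(stats::rnorm(nrow(lay) * 3), ncol = 3)
  r2 <- matrix(stats::rnorm(nrow(lay) * 3), ncol = 3)
  lhs <- invert(2 * r1 - 3 * r2)
  rhs <- 2 * invert(r1) - 3 * invert(r2)
  expect_equal(lhs, rhs, tolerance = 1e-10)
  # batched and per-sample processing agree
  per_sample <- vapply(1:3, function(t) invert(r1[, t, drop = FALSE])[, 1],
                       numeric(nrow(lhs)))
  expect_equal(invert(r1), per_sample, tolerance = 1e-12, ignore_attr = TRUE)
})
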