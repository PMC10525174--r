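test_that("hex shape functions: Kronecker, center, partition of unity", {
  corners <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
                   c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
  for (k in 1:8) {
    v <- hex_shape(corners[k, 1], corners[k, 2], corners[k, 3])$values
    expect_equal(v, as.numeric(seq_len(8) == k))
  }
  expect_equal(hex_shape(0, 0, 0)$values, rep(1 / 8, 8))
  set.seed(7)
  for (i in 1:20) {
    p <- stats::runif(3, -1, 1)
    sh <- hex_shape(p[1], p[2], p[3])
    expect_equal(sum(sh$values), 1, tolerance = 1e-12)
    expect_equal(colSums(sh$gradients), c(0, 0, 0), tolerance = 1e-12)
    expect_true(all(sh$values >= 0 & sh$values <= 1))
  }
  expect_error(hex_shape(1.2, 0, 0), "outside")
})

test_that("element stiffness matches the dense quadrature oracle", {
  # unit cube and randomly warped hexahedra (trilinear corner order)
  box <- build_box_mesh(1, 1, 1)
  cube <- box$nodes[box$elements[1, ], ]
  set.seed(21)
  warped <- cube + matrix(stats::runif(24, -0.12, 0.12), 8, 3)
  shapes <- list(list(cube, 3), list(cube * 2, 3), list(warped, 2))
  for (sc in shapes) {
    coords <- sc[[1]]
    Ke <- element_stiffness(coords, 1)
    Ko <- oracle_element_stiffness(coords, 1, n_gauss = sc[[2]])
    expect_lt(max(abs(Ke - Ko)) / max(abs(Ko)), 1e-10)
    expect_equal(Ke, t(Ke), tolerance = 1e-12)
    expect_lt(max(abs(rowSums(Ke))), 1e-12)
    expect_equal(element_stiffness(coords, 2), 2 * Ke, tolerance = 1e-12)
    expect_lt(max(abs(Ke %*% rep(1, 8))), 1e-12)   # constant in null space
  }
  # for the unit cube, the energy of u = x is int |grad u|^2 = 1
  expect_equal(as.numeric(t(cube[, 1]) %*% element_stiffness(cube, 1) %*%
                            cube[, 1]), 1, tolerance = 1e-12)
  bad <- cube; bad[c(1, 2), ] <- bad[c(2, 1), ]
  expect_error(element_stiffness(bad, 1), "Jacobian")
})

test_that("global assembly equals the dense oracle on small meshes", {
  for (mesh in list(build_box_mesh(2, 2, 2),
                    build_box_mesh(3, 2, 1, spacing = c(0.8, 1.3, 0.5)))) {
    K <- as.matrix(assemble_stiffness(mesh))
    Ko <- oracle_assemble_stiffness(mesh)
    expect_lt(max(abs(K - Ko)) / max(abs(Ko)), 1e-10)
    expect_lt(max(abs(K %*% rep(1, nrow(K)))), 1e-9)
    # energy positivity on random vectors
    set.seed(3)
    for (i in 1:10) {
      u <- stats::rnorm(nrow(K))
      expect_gte(as.numeric(t(u) %*% K %*% u), -1e-12)
    }
  }
})

test_that("disconnected mesh has a two-dimensional null space", {
  m1 <- build_box_mesh(1, 1, 1)
  m2 <- build_box_mesh(1, 1, 1, origin = c(5, 0, 0))
  ts <- tissue_table("medium", 1)
  fr <- matrix(1, 2, 1, dimnames = list(NULL, "medium"))
  mesh <- ecgi_mesh(rbind(m1$nodes, m2$nodes),
                    rbind(m1$elements, m2$elements + 8L),
                    ts, fr, c(FALSE, FALSE))
  ev <- eigen(as.matrix(assemble_stiffness(mesh)), symmetric = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-12 * max(ev)), 2L)
})

test_that("lumped masses conserve volume and area", {
  cube <- build_box_mesh(1, 1, 1)
  expect_equal(assemble_lumped_mass(cube, "volume"), rep(1 / 8, 8))
  mo <- assemble_lumped_mass(cube, "outer")
  expect_equal(sum(mo), 6)                       # total outer area
  # each face gives 1/4 per node; a cube corner touches 3 faces
  expect_equal(mo, rep(3 / 4, 8))
  torso <- small_torso()
  expect_equal(sum(assemble_lumped_mass(torso, "outer")),
               sum(torso$outer_faces$area), tolerance = 1e-10)
  expect_equal(sum(assemble_lumped_mass(torso, "volume")),
               sum(vapply(seq_len(nrow(torso$elements)), function(e) {
                 coords <- torso$nodes[torso$elements[e, ], ]
                 vol <- 0
                 for (q in directECGI:::.hex_gauss$shapes)
                   vol <- vol + det(t(q$gradients) %*% coords)
                 vol
               }, numeric(1))), tolerance = 1e-8)
  expect_error(assemble_lumped_mass(build_box_mesh(1, 1, 1), "epicardial"),
               "no epicardial")
})

test_that("admittance network mirrors the assembled stiffness", {
  cube <- build_box_mesh(1, 1, 1)
  K <- assemble_stiffness(cube, unit_scale = 1)
  net <- admittance_network(cube, K)
  expect_true(all(net$i < net$j))
  expect_false(anyDuplicated(net[, c("i", "j")]) > 0)
  for (r in sample(nrow(net), 5))
    expect_equal(net$Y[r], -K[net$i[r], net$j[r]], tolerance = 1e-12)
  # axis-aligned neighbours at spacing h have branch length h
  h <- 0.7
  cube2 <- build_box_mesh(1, 1, 1, spacing = h)
  net2 <- admittance_network(cube2, assemble_stiffness(cube2))
  axis <- abs(rowSums((cube2$nodes[net2$i, ] != cube2$nodes[net2$j, ]))) == 1
  expect_true(all(abs(net2$dL[axis] - h) < 1e-12))
  # two stacked identical elements double the admittance of shared-face branches
  two <- build_box_mesh(1, 2, 1)
  Kt <- assemble_stiffness(two, unit_scale = 1)
  # branch between nodes 1-2 (on the shared plane? pick an edge internal to
  # one element only): instead check additivity on the mid-plane edge 3-4
  shared <- which(two$nodes[, 2] == 1)
  i0 <- shared[1]; j0 <- shared[2]
  expect_equal(Kt[i0, j0],
               K[1, 2] * 2, tolerance = 1e-12)
})

test_that("homogeneous bar conductance matches sigma*A/L under refinement", {
  sigma <- 0.3
  ts <- tissue_table("m", sigma)
  for (n in c(4, 8)) {
    bar <- build_box_mesh(n, 1, 1, spacing = c(2 / n, 1, 1), tissues = ts)
    K <- assemble_stiffness(bar, unit_scale = 1)
    left <- which(bar$nodes[, 1] == 0)
    right <- which(bar$nodes[, 1] == 2)
    op <- forward_operator(bar, K, c(left, right))
    vals <- matrix(c(rep(0, length(left)), rep(1, length(right))), ncol = 1)
    u <- op(vals)
    flux <- sum((K %*% u)[right, ])        # total current into the 1 V end
    expect_equal(flux, sigma * 1 / 2, tolerance = 0.01)  # sigma * A / L
  }
})
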