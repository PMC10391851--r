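unit_cube <- function(h = 1) {
  corner <- cbind(c(0, 1, 1, 0, 0, 1, 1, 0),
                  c(0, 0, 1, 1, 0, 0, 1, 1),
                  c(0, 0, 0, 0, 1, 1, 1, 1))
  corner * h
}

test_that("element stiffness is symmetric PSD with six rigid-body modes", {
  for (lm in list(c(0, 0.5), lame_parameters(12000, 0.3))) {
    K <- element_stiffness(unit_cube(), lm[1], lm[2])
    expect_equal(K, t(K))
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sum(abs(ev) < 1e-8 * max(ev)), 6)
    expect_true(all(ev > -1e-8 * max(ev)))
  }
  # inverted element rejected
  flipped <- unit_cube(); flipped[, 3] <- -flipped[, 3]
  expect_error(element_stiffness(flipped, 0, 0.5), "Jacobian")
})

test_that("uniaxial strain energy and edge-length scaling match closed forms", {
  K <- element_stiffness(unit_cube(), 0, 0.5)      # E = 1, nu = 0
  u <- as.vector(t(cbind(0, 0, unit_cube()[, 3]))) # unit uniaxial stretch
  expect_equal(as.numeric(0.5 * t(u) %*% K %*% u), 0.5, tolerance = 1e-12)
  K2 <- element_stiffness(unit_cube(2), 0, 0.5)
  expect_equal(K2, 2 * K, tolerance = 1e-12)       # K scales with edge length
})

test_that("assembly reduces to the element matrix and respects equilibrium", {
  tab <- bar_table()
  m1 <- voxel_to_hexmesh(make_bar_model(1, 1, 1))
  sys1 <- assemble(m1, tab)
  lm <- lame_parameters(tab$entries$peek)
  # global matrix equals the element matrix up to the node-numbering
  # permutation of the mesh
  gdofs <- as.vector(t(cbind(3 * m1$elem[1, ] - 2, 3 * m1$elem[1, ] - 1,
                             3 * m1$elem[1, ])))
  expect_equal(as.matrix(sys1$K)[gdofs, gdofs],
               element_stiffness(unit_cube(), lm["lambda"], lm["mu"]),
               ignore_attr = TRUE, tolerance = 1e-12)
  # rigid translation produces no force: row sums vanish
  m2 <- voxel_to_hexmesh(make_bar_model(2, 1, 1))
  sys2 <- assemble(m2, tab)
  expect_lt(max(abs(Matrix::rowSums(sys2$K))), 1e-9)
  expect_equal(nrow(sys2$K), 3 * m2$n_nodes)
  # missing material role is an error
  tab2 <- tab; tab2$entries$peek <- NULL
  expect_error(assemble(m2, tab2), "lacks roles")
})

test_that("axial load lumping conserves the resultant with 1:2:4 weights", {
  mesh <- voxel_to_hexmesh(make_bar_model(2, 2, 1))
  sys <- assemble(mesh, bar_table())
  sys <- apply_axial_load(sys, 100)
  fz <- sys$f[seq(3, sys$ndof, by = 3)]
  expect_equal(sum(fz), -100, tolerance = 1e-12)
  expect_equal(sum(sys$f[-seq(3, sys$ndof, by = 3)]), 0)
  top <- mesh$sets$superior_C4_nodes
  w <- fz[top] / max(abs(fz[top])) * 4
  expect_setequal(round(sort(unique(-w)), 10), c(1, 2, 4))
})

test_that("homogeneous bar matches delta = FL/EA and sigma = F/A", {
  # 10 mm bar, 14 x 16 mm cross-section, E = 3600 MPa, nu = 0, F = 100 N
  mesh <- voxel_to_hexmesh(make_bar_model(14, 16, 10))
  tab <- bar_table(E1 = 3600)
  sys <- assemble(mesh, tab)
  sys <- fix_bar_base(sys, mesh)
  sys <- apply_axial_load(sys, 100)
  sol <- solve_system(sys)
  delta <- -mean(sol$U[mesh$sets$superior_C4_nodes, 3])
  expect_equal(delta, 100 * 10 / (3600 * 14 * 16), tolerance = 0.005)
  expect_lte(sol$residual_rel, 1e-10)
  expect_lte(sol$reaction_balance_rel, 1e-8)
  fields <- recover_stress(mesh, sol, tab)
  expect_equal(unname(fields$stress[, "zz"]),
               rep(-100 / 224, mesh$n_elem), tolerance = 0.005)
  expect_lt(max(abs(fields$stress[, c("xx", "yy", "xy", "yz", "zx")])), 1e-6)
  # linearity: doubled load doubles the field
  sys2 <- assemble(mesh, tab)
  sys2 <- fix_bar_base(sys2, mesh)
  sys2 <- apply_axial_load(sys2, 200)
  sol2 <- solve_system(sys2)
  expect_equal(sol2$U, 2 * sol$U, tolerance = 1e-9)
  # zero load gives the zero solution
  sys0 <- assemble(mesh, tab)
  sys0 <- fix_bar_base(sys0, mesh)
  sys0 <- apply_axial_load(sys0, 0)
  expect_equal(max(abs(solve_system(sys0)$U)), 0)
})

test_that("two-material stacked bar matches the springs-in-series form", {
  model <- make_bar_model(6, 8, 10)
  model$labels[, , 6:10] <- match("cancellous", ROLE_NAMES)
  mesh <- voxel_to_hexmesh(model)
  tab <- bar_table(E1 = 3600, E2 = 450)
  sys <- assemble(mesh, tab)
  sys <- fix_bar_base(sys, mesh)
  sys <- apply_axial_load(sys, 100)
  sol <- solve_system(sys)
  delta <- -mean(sol$U[mesh$sets$superior_C4_nodes, 3])
  A <- 6 * 8
  expect_equal(delta, 100 * 5 / A * (1 / 3600 + 1 / 450), tolerance = 0.005)
})

test_that("refining the mesh leaves the affine bar solution unchanged", {
  delta_h <- sapply(c(1, 0.5), function(h) {
    mesh <- voxel_to_hexmesh(make_bar_model(6 / h, 8 / h, 8 / h, h = h))
    sys <- assemble(mesh, bar_table(E1 = 3600))
    sys <- fix_bar_base(sys, mesh)
    sys <- apply_axial_load(sys, 100)
    -mean(solve_system(sys)$U[mesh$sets$superior_C4_nodes, 3])
  })
  expect_lt(abs(delta_h[2] / delta_h[1] - 1), 1e-3)
})

test_that("patch test: affine boundary data is reproduced exactly inside", {
  mesh <- voxel_to_hexmesh(make_bar_model(3, 3, 3))
  tab <- bar_table(E1 = 1000)
  tab$entries$peek$poisson_ratio <- 0.3
  sys <- assemble(mesh, tab)
  A <- matrix(c(1e-3, 2e-4, -1e-4,
                3e-4, -5e-4, 2e-4,
                1e-4, 4e-4, 8e-4), 3, 3, byrow = TRUE)
  b <- c(1e-3, -2e-3, 5e-4)
  affine <- t(A %*% t(mesh$nodes)) + rep(b, each = mesh$n_nodes)
  on_boundary <- apply(mesh$nodes, 1, function(p)
    any(p == 0) || any(p == 3))
  bn <- which(on_boundary)
  sys <- fix_dofs(sys, as.vector(t(cbind(3 * bn - 2, 3 * bn - 1, 3 * bn))),
                  as.vector(t(affine[bn, ])))
  sol <- solve_system(sys)
  expect_equal(sol$U, affine, tolerance = 1e-10, ignore_attr = TRUE)
  # and the recovered stress field is constant
  fields <- recover_stress(mesh, sol, tab)
  expect_lt(max(apply(fields$stress, 2, function(s) diff(range(s)))), 1e-10)
})

test_that("rigid motions produce zero stress", {
  mesh <- voxel_to_hexmesh(make_bar_model(2, 2, 2))
  tab <- bar_table()
  U <- matrix(rep(c(0.3, -0.2, 0.5), each = mesh$n_nodes), ncol = 3)
  fields <- recover_stress(mesh, U, tab)
  expect_lt(max(abs(fields$stress)), 1e-12)
  expect_lt(max(fields$von_mises), 1e-12)
})

test_that("Von Mises identities and rotation invariance hold", {
  expect_equal(von_mises(c(5, 0, 0, 0, 0, 0)), 5)
  expect_equal(von_mises(c(-3, 0, 0, 0, 0, 0)), 3)
  expect_equal(von_mises(c(7, 7, 7, 0, 0, 0)), 0)        # hydrostatic
  expect_equal(von_mises(c(0, 0, 0, 2, 0, 0)), 2 * sqrt(3))  # pure shear
  set.seed(42)
  for (i in 1:100) {
    S <- matrix(rnorm(9), 3, 3); S <- (S + t(S)) / 2
    qr_ <- qr(matrix(rnorm(9), 3, 3))
    Q <- qr.Q(qr_)
    expect_equal(von_mises(Q %*% S %*% t(Q)), von_mises(S),
                 tolerance = 1e-10)
  }
  expect_true(all(von_mises(matrix(rnorm(60), 10, 6)) >= 0))
})

test_that("an unconstrained system is rejected", {
  mesh <- voxel_to_hexmesh(make_bar_model(2, 2, 2))
  sys <- assemble(mesh, bar_table())
  expect_error(solve_system(sys), "rigid-body")
})
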