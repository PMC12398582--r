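## Ellipsoidal mesh generation, cavity volume, and rule-based fibers.

test_that("quadrature rules integrate monomials exactly to their degree", {
  exact_tet <- function(a, b, c)
    factorial(a) * factorial(b) * factorial(c) / factorial(a + b + c + 3)
  exact_tri <- function(a, b) factorial(a) * factorial(b) / factorial(a + b + 2)
  q27 <- tet_quadrature(3)
  q14 <- tet_quadrature14()
  for (m in list(c(0, 0, 0), c(2, 1, 0), c(1, 1, 1), c(4, 0, 0),
                 c(2, 2, 0), c(1, 3, 0))) {
    ref <- exact_tet(m[1], m[2], m[3])
    for (q in list(q27, q14)) {
      v <- sum(q$weights * q$points[, 1]^m[1] * q$points[, 2]^m[2] *
                 q$points[, 3]^m[3])
      expect_equal(v, ref, tolerance = 1e-12)
    }
  }
  qt <- tri_quadrature()
  for (m in list(c(0, 0), c(2, 2), c(4, 0), c(3, 1))) {
    v <- sum(qt$weights * qt$points[, 1]^m[1] * qt$points[, 2]^m[2])
    expect_equal(v, exact_tri(m[1], m[2]), tolerance = 1e-12)
  }
})

test_that("P2 shape functions interpolate and partition unity", {
  xi <- matrix(runif(30), 10, 3) / 3
  sh <- tet10_shape(xi)
  expect_equal(rowSums(sh$N), rep(1, 10), tolerance = 1e-12)
  expect_equal(apply(sh$dN, c(1, 3), sum), matrix(0, 10, 3),
               tolerance = 1e-12)
  ## quadratic completeness: interpolate x^2 exactly
  nodes_ref <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                     c(.5, 0, 0), c(.5, .5, 0), c(0, .5, 0), c(0, 0, .5),
                     c(.5, 0, .5), c(0, .5, .5))
  f <- nodes_ref[, 1]^2 + 2 * nodes_ref[, 2] * nodes_ref[, 3]
  fx <- drop(sh$N %*% f)
  expect_equal(fx, xi[, 1]^2 + 2 * xi[, 2] * xi[, 3], tolerance = 1e-12)
})

test_that("unloaded cavity volume matches the truncated-ellipsoid geometry", {
  g <- lv_geometry() # printed healthy dimensions
  analytic_ml <- (2 / 3) * pi * g$a_endo^2 * g$c_endo / lv_units$mL
  fx <- fe_fixture()
  V <- cavity_volume(fx$fe) / lv_units$mL
  expect_equal(V, analytic_ml, tolerance = 0.01)
  ## the coarse fixture closes the check at 5% against the nominal 75 mL
  expect_equal(V, 75, tolerance = 0.05)
  ## wall volume agrees with the analytic shell volume
  wall_ml <- (2 / 3) * pi * (g$a_epi^2 * g$c_epi - g$a_endo^2 * g$c_endo) /
    lv_units$mL
  expect_equal(mesh_wall_volume(fx$mesh) / lv_units$mL, wall_ml,
               tolerance = 0.01)
})

test_that("cavity volume scales cubically and ignores in-plane rigid motion", {
  g2 <- lv_geometry(length_cm = 2 * 7.3, outer_diameter_cm = 2 * 7.2,
                    wall_thickness_cm = 2 * 1.3)
  m1 <- build_ellipsoid_mesh(lv_geometry(), "mini")
  m2 <- build_ellipsoid_mesh(g2, "mini")
  expect_equal(cavity_volume(fe_setup(m2)), 8 * cavity_volume(fe_setup(m1)),
               tolerance = 1e-9)
  ## rigid in-plane translation leaves the enclosed volume unchanged
  fe <- fe_mini()
  u <- rep(c(0.003, -0.002, 0), nrow(fe$mesh$nodes))
  expect_equal(cavity_volume(fe, u), cavity_volume(fe), tolerance = 1e-12)
  ## uniform dilation of all nodes scales the volume cubically
  u_dil <- 0.1 * as.numeric(t(fe$mesh$nodes))
  expect_equal(cavity_volume(fe, u_dil), 1.1^3 * cavity_volume(fe),
               tolerance = 1e-12)
})

test_that("spherical-cap limit reproduces the analytic hemisphere volume", {
  g <- lv_geometry(length_cm = 5, outer_diameter_cm = 10,
                   wall_thickness_cm = 1, apical_thickness_cm = 1)
  fe <- fe_setup(build_ellipsoid_mesh(g, "coarse"))
  expect_equal(cavity_volume(fe), (2 / 3) * pi * 0.04^3, tolerance = 5e-3)
})

test_that("rule-based fibers follow the linear transmural helix rule", {
  expect_equal(helix_angle_rule(0), 60)
  expect_equal(helix_angle_rule(1), -60)
  expect_equal(helix_angle_rule(0.5), 0)
  fx <- fe_fixture()
  fib <- assign_rule_based_fibers(fx$fe)
  ## orthonormal right-handed triads everywhere
  dot_fs <- rowSums(fib$f0 * fib$s0)
  dot_fn <- rowSums(fib$f0 * fib$n0)
  expect_lt(max(abs(dot_fs)), 1e-10)
  expect_lt(max(abs(dot_fn)), 1e-10)
  expect_equal(rowSums(fib$f0^2), rep(1, fx$fe$n_qp), tolerance = 1e-10)
  dets <- fib$f0[, 1] * (fib$s0[, 2] * fib$n0[, 3] - fib$s0[, 3] * fib$n0[, 2]) -
    fib$f0[, 2] * (fib$s0[, 1] * fib$n0[, 3] - fib$s0[, 3] * fib$n0[, 1]) +
    fib$f0[, 3] * (fib$s0[, 1] * fib$n0[, 2] - fib$s0[, 2] * fib$n0[, 1])
  expect_equal(dets, rep(1, fx$fe$n_qp), tolerance = 1e-10)
  ## measured helix angle reproduces the rule away from the apex cap
  ang <- helix_transverse_angles(fib$f0, fib$basis)
  ok <- !fib$degenerate
  expect_equal(ang$helix_deg[ok], helix_angle_rule(fx$fe$t_qp)[ok],
               tolerance = 1e-6)
  expect_equal(ang$transverse_deg[ok], rep(0, sum(ok)), tolerance = 1e-6)
  ## the rule is antisymmetric about midwall: helix(t) = -helix(1 - t)
  expect_equal(helix_angle_rule(fx$fe$t_qp), -helix_angle_rule(1 - fx$fe$t_qp))
  expect_true(all(abs(ang$helix_deg[ok]) <= 60 + 1e-9))
})

test_that("transmural coordinate spans endo to epi monotonically", {
  fx <- fe_fixture()
  expect_true(all(fx$fe$t_qp >= 0 & fx$fe$t_qp <= 1))
  mesh <- fx$mesh
  expect_true(all(mesh$t_node[unique(as.vector(mesh$endo_faces))] < 1e-9))
  expect_true(all(mesh$t_node[unique(as.vector(mesh$epi_faces))] > 1 - 1e-9))
})
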