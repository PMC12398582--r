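## Passive and active stress laws.

test_that("bulk stress matches the hand-worked uniaxial fiber strain case", {
  ## E_ff = 0.1 only, normal-tissue constants: Q = 8 * 0.01 = 0.08,
  ## S_ff = 200 e^0.08 * 8 * 0.1 = 173.3 Pa
  fr <- fiber_frame(c(1, 0, 0), c(0, 1, 0))
  E <- diag(c(0.1, 0, 0))
  S <- bulk_stress(E, fr, bulk_params())
  expect_equal(S[1, 1], 200 * exp(0.08) * 8 * 0.1, tolerance = 1e-12)
  expect_equal(S[1, 1], 173.3, tolerance = 1e-3)
  expect_equal(S[2, 2], 0)
  ## zero strain, zero stress
  expect_equal(bulk_stress(matrix(0, 3, 3), fr, bulk_params()),
               matrix(0, 3, 3))
})

test_that("bulk stress equals numeric differentiation of the strain energy", {
  set.seed(11)
  pars <- bulk_params()
  for (k in 1:20) {
    fr <- fiber_frame(rnorm(3), rnorm(3))
    E <- random_strain(0.08)
    S <- bulk_stress(E, fr, pars)
    S_fd <- fd_stress(function(EE) psi_bulk_ref(EE, fr, pars), E)
    expect_equal(S, S_fd, tolerance = 1e-6)
  }
})

test_that("myofiber stress is tension-only and matches its derivative", {
  pars <- myofiber_params() # C_1 = 250 Pa, C_2 = 15
  fr <- fiber_frame(c(1, 0, 0), c(0, 1, 0))
  mk <- function(lam) kinematic_point(diag(c(lam, 1 / sqrt(lam),
                                             1 / sqrt(lam))), c(1, 0, 0))
  ## compression and the unstretched state carry no fiber stress
  expect_equal(myofiber_passive_stress(mk(1), fr, pars), matrix(0, 3, 3))
  expect_equal(myofiber_passive_stress(mk(0.9), fr, pars), matrix(0, 3, 3))
  ## alpha = 1.1: Psi' = 2*250*15*0.1*e^0.15; S_ff = Psi'/1.1
  S <- myofiber_passive_stress(mk(1.1), fr, pars)
  expect_equal(S[1, 1], 2 * 250 * 15 * 0.1 * exp(15 * 0.01) / 1.1,
               tolerance = 1e-12)
  expect_equal(S[1, 1], 792.2, tolerance = 1e-3)
  expect_equal(S[2, 2], 0)
  ## numeric-differentiation oracle on random stretched states
  set.seed(3)
  for (k in 1:10) {
    f0 <- rnorm(3); f0 <- f0 / sqrt(sum(f0^2))
    E <- random_strain(0.05) + 0.08 * tcrossprod(f0) # bias to stretch
    a2 <- 1 + 2 * drop(t(f0) %*% E %*% f0)
    if (a2 <= 1) next
    F <- chol(diag(3) + 2 * E) # upper-triangular F with F'F = C
    pt <- kinematic_point(F, f0)
    frk <- fiber_frame(f0, if (abs(f0[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0))
    S <- myofiber_passive_stress(pt, frk, pars)
    S_fd <- fd_stress(function(EE) psi_myo_ref(EE, f0, pars), E)
    expect_equal(S, S_fd, tolerance = 1e-5)
  }
})

test_that("active stress tensor is the rank-1 fiber projection", {
  expect_equal(active_stress_tensor(0, c(0, 0, 1)), matrix(0, 3, 3))
  S <- active_stress_tensor(1000, c(1, 0, 0))
  expect_equal(S, diag(c(1000, 0, 0)))
  expect_equal(sum(diag(S)), 1000)
  ## rotation equivariance
  set.seed(5)
  for (k in 1:10) {
    R <- random_rotation()
    f0 <- c(0.36, 0.48, 0.8)
    S1 <- active_stress_tensor(123, as.numeric(R %*% f0))
    S2 <- R %*% active_stress_tensor(123, f0) %*% t(R)
    expect_equal(S1, S2, tolerance = 1e-12)
  }
})

test_that("volumetric term reproduces -p J C^{-1} and its energy derivative", {
  set.seed(9)
  F <- diag(3) + matrix(rnorm(9, sd = 0.05), 3, 3)
  if (det(F) < 0) F <- -F
  pt <- kinematic_point(F, c(1, 0, 0))
  p <- 37.5
  Sv <- volumetric_stress(pt, p)
  expect_equal(Sv, -p * pt$J * solve(pt$C), tolerance = 1e-12)
  ## derivative of Psi_vol = -p (J - 1) w.r.t. E at fixed p
  psi_vol <- function(E) {
    C <- diag(3) + 2 * E
    -p * (sqrt(det(C)) - 1)
  }
  S_fd <- fd_stress(psi_vol, pt$E)
  expect_equal(Sv, S_fd, tolerance = 1e-5)
})

test_that("total stress composes additively and vanishes at rest", {
  fr <- fiber_frame(c(1, 0, 0), c(0, 1, 0))
  pt <- kinematic_point(diag(3), c(1, 0, 0))
  expect_equal(total_stress(pt, fr, bulk_params(), myofiber_params()),
               matrix(0, 3, 3))
  S <- total_stress(pt, fr, bulk_params(), myofiber_params(),
                    f_active = 500, p = 20)
  expect_equal(S, diag(c(500, 0, 0)) - 20 * diag(3))
})

test_that("frame objectivity: consistent rotation leaves stress invariants unchanged", {
  set.seed(21)
  pars <- bulk_params()
  for (k in 1:8) {
    fr <- fiber_frame(rnorm(3), rnorm(3))
    E <- random_strain(0.06)
    R <- random_rotation()
    fr_rot <- fiber_frame(as.numeric(R %*% unclass(fr)[, 1]),
                          as.numeric(R %*% unclass(fr)[, 2]))
    S1 <- bulk_stress(E, fr, pars)
    S2 <- bulk_stress(R %*% E %*% t(R), fr_rot, pars)
    expect_equal(sort(eigen(S2, symmetric = TRUE)$values),
                 sort(eigen(S1, symmetric = TRUE)$values),
                 tolerance = 1e-9)
  }
})

test_that("equal exponents make the bulk law isotropic (fibrous tissue)", {
  set.seed(13)
  tab <- material_table()
  expect_equal(tab$fibrous$bulk$b_ff, tab$fibrous$bulk$b_xx)
  expect_equal(tab$fibrous$bulk$b_ff, tab$fibrous$bulk$b_fs)
  expect_equal(tab$fibrous$myofiber$C_1, 0)
  expect_equal(tab$fibrous$xb_density, 0)
  for (k in 1:10) {
    fr <- fiber_frame(rnorm(3), rnorm(3))
    E <- random_strain(0.06)
    S <- bulk_stress(E, fr, tab$fibrous$bulk)
    ## stress commutes with strain: shared eigenvectors
    expect_lt(max(abs(S %*% E - E %*% S)), 1e-8 * max(abs(S)))
    ## the fibrous row has no myofiber spring for any stretch
    pt <- kinematic_point(diag(c(1.2, 1, 1 / 1.2)), unclass(fr)[, 1])
    expect_equal(myofiber_passive_stress(pt, fr, tab$fibrous$myofiber),
                 matrix(0, 3, 3))
  }
})

test_that("fiber frame constructor enforces orthonormal right-handed triads", {
  fr <- fiber_frame(c(2, 0, 0), c(0.5, 3, 0))
  Q <- unclass(fr)
  expect_equal(crossprod(Q), diag(3), tolerance = 1e-12)
  expect_equal(det(Q), 1, tolerance = 1e-12)
  expect_error(fiber_frame(c(1, 0, 0), c(2, 0, 0)), "parallel")
})
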