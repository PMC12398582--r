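## Stress-driven fiber reorientation.

test_that("per-step blending fraction is dt/kappa", {
  prm <- reorientation_params() # kappa = 4000 ms
  expect_equal(1 / prm$kappa_ms, 2.5e-4)
  ## hand evaluation of one update on the worked 2D case
  f0 <- c(1, 1, 0) / sqrt(2)
  S <- diag(c(2, 1, 1))
  tr <- drop(S %*% f0)
  tru <- tr / sqrt(sum(tr^2))
  expect_equal(tru[1:2], c(0.8944, 0.4472), tolerance = 1e-4)
  upd <- reorient_step(f0, S, dt_ms = 1, prm)
  raw <- f0 + 2.5e-4 * (tru - f0)
  expect_equal(upd$f0, raw / sqrt(sum(raw^2)), tolerance = 1e-14)
  expect_false(upd$skipped)
})

test_that("eigenvectors of the stress are fixed points", {
  S <- diag(c(5, 2, 1))
  for (k in 1:3) {
    e <- diag(3)[, k]
    expect_equal(reorient_step(e, S, 1)$f0, e)
  }
  ## also under the axial convention for -f0
  expect_equal(reorient_step(-diag(3)[, 1], S, 1)$f0, -diag(3)[, 1])
})

test_that("iteration converges to the dominant eigenvector (dense-eigen oracle)", {
  set.seed(31)
  for (k in 1:5) {
    ## random orientation with a guaranteed spectral gap (the convergence
    ## rate of the update is proportional to the gap)
    R <- random_rotation()
    S <- R %*% diag(c(3, 1, 0.5) * 1e4) %*% t(R)
    ev <- eigen(S, symmetric = TRUE)
    f <- rnorm(3); f <- f / sqrt(sum(f^2))
    for (i in 1:7000) f <- reorient_step(f, S, dt_ms = 10, eps = 1e-300)$f0
    v1 <- ev$vectors[, 1]
    expect_lt(reorientation_angle(f, v1), 0.5) # degrees
  }
})

test_that("update is invariant under the axial ambiguity f0 -> -f0", {
  set.seed(5)
  S <- random_symm(100)
  f0 <- rnorm(3); f0 <- f0 / sqrt(sum(f0^2))
  a <- reorient_step(f0, S, 1)$f0
  b <- reorient_step(-f0, S, 1)$f0
  expect_equal(a, -b, tolerance = 1e-14)
})

test_that("unloaded points are skipped, not rotated", {
  f0 <- c(0, 0, 1)
  upd <- reorient_step(f0, matrix(0, 3, 3), 1)
  expect_true(upd$skipped)
  expect_equal(upd$f0, f0)
})

test_that("halving dt leaves the trajectory consistent to first order", {
  set.seed(8)
  S <- random_symm(1e3) + diag(3) * 2e3
  f0 <- c(1, 0, 0)
  walk <- function(dt, n) {
    f <- f0
    for (i in seq_len(n)) f <- reorient_step(f, S, dt)$f0
    f
  }
  f_ref <- walk(0.5, 4000) # fine reference
  e1 <- reorientation_angle(walk(8, 250), f_ref)
  e2 <- reorientation_angle(walk(4, 500), f_ref)
  expect_lt(e2, e1) # first-order error shrinks with dt
  expect_gt(e1 / max(e2, 1e-12), 1.5) # roughly linear in dt
})

test_that("rebuild_frame keeps orthonormal right-handed triads and continuity", {
  set.seed(12)
  fr <- list(f0 = c(1, 0, 0), s0 = c(0, 1, 0), n0 = c(0, 0, 1))
  for (i in 1:600) {
    dn <- rnorm(3, sd = 5e-3)
    f_new <- fr$f0 + dn
    f_new <- f_new / sqrt(sum(f_new^2))
    fr2 <- rebuild_frame(f_new, fr)
    expect_equal(sum(fr2$f0 * fr2$s0), 0, tolerance = 1e-10)
    expect_equal(sum(fr2$f0 * fr2$n0), 0, tolerance = 1e-10)
    expect_equal(sqrt(sum(fr2$s0^2)), 1, tolerance = 1e-10)
    det3 <- det(cbind(fr2$f0, fr2$s0, fr2$n0))
    expect_equal(det3, 1, tolerance = 1e-10)
    fr <- fr2
  }
  ## unchanged fiber leaves the frame unchanged
  fr3 <- rebuild_frame(fr$f0, fr)
  expect_equal(fr3$s0, fr$s0, tolerance = 1e-12)
})

test_that("field update matches the scalar per-point loop on a synthetic stress field", {
  fx <- make_fixtures("synthetic-stress-field")
  fe <- fx$fe
  fib <- assign_rule_based_fibers(fe)
  fib$f0_init <- fib$f0
  prm <- reorientation_params(kappa_ms = 100)
  up <- reorientation_field_update(fib, fx$S_voigt, dt_ms = 10, prm)
  ## independent scalar-loop oracle
  n_bad <- 0
  for (iq in seq_len(fe$n_qp)) {
    S <- matrix(0, 3, 3)
    v <- fx$S_voigt[iq, ]
    S[1, 1] <- v[1]; S[2, 2] <- v[2]; S[3, 3] <- v[3]
    S[2, 3] <- S[3, 2] <- v[4]; S[1, 3] <- S[3, 1] <- v[5]
    S[1, 2] <- S[2, 1] <- v[6]
    ref <- reorient_step(fib$f0[iq, ], S, 10, prm)
    fr_ref <- rebuild_frame(ref$f0, list(s0 = fib$s0[iq, ], n0 = fib$n0[iq, ]))
    if (max(abs(fr_ref$f0 - up$f0[iq, ])) > 1e-12 ||
        max(abs(fr_ref$s0 - up$s0[iq, ])) > 1e-12) n_bad <- n_bad + 1
  }
  expect_equal(n_bad, 0)
  ## long-run iteration aligns fibers with the constructed dominant field
  for (i in 1:2500) up <- reorientation_field_update(up, fx$S_voigt, 10, prm)
  ang <- reorientation_angle(up$f0, fx$dominant)
  expect_lt(stats::median(ang), 1)
})

test_that("cumulative angle is zero when stress is everywhere fiber-aligned", {
  fx <- fe_fixture()
  fib <- assign_rule_based_fibers(fx$fe)
  fib$f0_init <- fib$f0
  ## stress = rank-1 tension along the current fiber at every point
  Sv <- cbind(fib$f0[, 1]^2, fib$f0[, 2]^2, fib$f0[, 3]^2,
              fib$f0[, 2] * fib$f0[, 3], fib$f0[, 1] * fib$f0[, 3],
              fib$f0[, 1] * fib$f0[, 2]) * 1e4
  up <- reorientation_field_update(fib, Sv, 1, reorientation_params())
  expect_lt(max(cumulative_reorientation_angle(up)), 1e-6)
})
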