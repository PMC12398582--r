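## Shared test utilities: independent oracles and small builders.

## random rotation matrix (uniform via QR of a Gaussian matrix)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

## random symmetric 3x3 with given scale
random_symm <- function(scale = 1) {
  A <- matrix(rnorm(9, sd = scale), 3, 3)
  (A + t(A)) / 2
}

## random admissible Green-Lagrange strain (moderate, keeps exponents sane)
random_strain <- function(scale = 0.05) random_symm(scale)

## central finite difference of a scalar energy w.r.t. the symmetric
## strain tensor: returns dPsi/dE as a symmetric 3x3
fd_stress <- function(psi, E, h = 1e-6) {
  S <- matrix(0, 3, 3)
  for (i in 1:3) for (j in i:3) {
    dE <- matrix(0, 3, 3)
    if (i == j) dE[i, j] <- 1 else dE[i, j] <- dE[j, i] <- 0.5
    Sij <- (psi(E + h * dE) - psi(E - h * dE)) / (2 * h)
    S[i, j] <- S[j, i] <- Sij
  }
  S
}

## Guccione bulk strain energy evaluated in the fiber frame (independent
## of the package's stress code path)
psi_bulk_ref <- function(E, frame, params) {
  Q <- unclass(frame)
  Ef <- t(Q) %*% E %*% Q
  B <- matrix(c(params$b_ff, params$b_fs, params$b_fs,
                params$b_fs, params$b_xx, params$b_xx,
                params$b_fs, params$b_xx, params$b_xx), 3, 3, byrow = TRUE)
  params$C / 2 * (exp(sum(B * Ef^2)) - 1)
}

## myofiber strain energy as a function of E (through alpha)
psi_myo_ref <- function(E, f0, params) {
  a2 <- 1 + 2 * drop(t(f0) %*% E %*% f0)
  a <- sqrt(a2)
  if (a <= 1) 0 else params$C_1 * exp(params$C_2 * (a - 1)^2)
}

## brute-force cross-bridge reference integrator: plain R, explicit Euler
## at a very fine step, same fluxes written independently of the C++ path
xb_euler_reference <- function(state, ca_fun, params, t_end, dt,
                               f_feedback = TRUE, track_peak = FALSE) {
  x <- seq(-10, 10)
  xm <- x * 1e-9
  w <- exp(-params$k_cb * xm^2 / (2 * params$kBT))
  s <- as.numeric(state)
  f_active <- function(s)
    params$N_0 * params$k_cb * sum(s[5:25] * (x + params$x_ps) * 1e-9)
  n <- round(t_end / dt)
  f <- 0
  f_peak <- 0
  for (i in seq_len(n)) {
    ca <- ca_fun(i * dt)
    Non <- s[2]; Nb <- sum(s[5:25])
    Jon <- params$k_on * ca * (1 - Non) * (1 + params$k_coop * Non)
    Joff <- params$k_off * (Non - Nb) * (1 + params$k_coop * (1 - Non))
    ft <- if (f_feedback) max(f, 0) else 0
    J1 <- params$k_1 * (1 + params$k_force * ft) * s[3]
    J2 <- params$k_2 * s[4]
    J3 <- params$k_3 * w * (Non - Nb) * s[4]
    J4 <- (params$k_4_0 + params$k_4_1 * x^4) * s[5:25]
    ds <- c(-Jon + Joff, Jon - Joff,
            -J1 + J2, (J1 + sum(J4)) - (J2 + sum(J3)), J3 - J4)
    s <- s + dt * ds
    f <- f_active(s)
    if (track_peak) f_peak <- max(f_peak, f)
  }
  list(state = s, F_active = f, F_peak = f_peak)
}

## a cached coarse FE fixture shared across test files
fe_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_fixtures("coarse-mesh")
    cache
  }
})

## a cached mini FE fixture for the expensive mechanics tests
fe_mini <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      mesh <- build_ellipsoid_mesh(lv_geometry(), "mini")
      cache <<- fe_setup(mesh)
    }
    cache
  }
})
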