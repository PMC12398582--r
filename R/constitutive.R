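## Passive and active stress laws of the myocardium.
##
## All stresses are 2nd Piola-Kirchhoff tensors in the reference
## configuration.  The passive response decomposes into a volumetric
## Lagrange-multiplier term (exact incompressibility), a transversely
## isotropic Guccione bulk term, and an exponential tension-only myofiber
## spring; the active stress is the sarcomere force projected along the
## reference fiber direction.

#' Guccione bulk material parameters
#'
#' Strain energy C/2 (e^Q - 1) with
#' Q = b_ff E_ff^2 + b_xx (E_ss^2 + E_nn^2 + E_sn^2 + E_ns^2)
#'   + b_fs (E_fs^2 + E_sf^2 + E_fn^2 + E_nf^2),
#' E expressed in the local fiber/sheet/sheet-normal frame.  Material tables
#' elsewhere name the exponents b_f, b_t, b_fs; they map to b_ff, b_xx,
#' b_fs here (standard Guccione notation).
#'
#' @param C stress scale (Pa).
#' @param b_ff,b_xx,b_fs dimensionless exponents.
#' @return object of class \code{bulk_params}.
#' @export
bulk_params <- function(C = 200, b_ff = 8, b_xx = 3.58, b_fs = 1.63) {
  if (C <= 0) stop("C must be > 0")
  if (any(c(b_ff, b_xx, b_fs) < 0)) stop("exponents must be >= 0")
  structure(list(C = C, b_ff = b_ff, b_xx = b_xx, b_fs = b_fs),
            class = "bulk_params")
}

#' Myofiber passive parameters
#'
#' Tension-only exponential fiber spring with energy
#' C_1 e^{C_2 (alpha - 1)^2} for fiber stretch alpha > 1 and zero otherwise
#' (the printed form carries a constant energy offset C_1 at alpha = 1; the
#' stress comes from the derivative, so the offset is inert).  C_1 = 0
#' disables the term (fibrous regions).
#'
#' @param C_1 stress scale (Pa).
#' @param C_2 dimensionless exponent.
#' @return object of class \code{myofiber_params}.
#' @export
myofiber_params <- function(C_1 = 250, C_2 = 15) {
  if (C_1 < 0 || C_2 < 0) stop("C_1 and C_2 must be >= 0")
  structure(list(C_1 = C_1, C_2 = C_2), class = "myofiber_params")
}

#' Orthonormal fiber frame
#'
#' Right-handed triad (fiber f0, sheet s0, sheet-normal n0) in the
#' reference configuration.
#'
#' @param f0,s0,n0 length-3 vectors; \code{n0} defaults to \code{f0 x s0}.
#' @return object of class \code{fiber_frame} (3x3 matrix with columns f0,
#'   s0, n0).
#' @export
fiber_frame <- function(f0, s0, n0 = NULL) {
  f0 <- f0 / sqrt(sum(f0^2))
  s0 <- s0 - sum(s0 * f0) * f0
  ns <- sqrt(sum(s0^2))
  if (ns < 1e-12) stop("s0 is parallel to f0")
  s0 <- s0 / ns
  if (is.null(n0)) n0 <- cross3(f0, s0)
  Q <- unname(cbind(f0, s0, n0))
  if (max(abs(crossprod(Q) - diag(3))) > 1e-10)
    stop("frame is not orthonormal")
  if (det(Q) < 0) stop("frame is not right-handed")
  structure(Q, class = "fiber_frame")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Kinematic quantities at a material point
#'
#' @param F 3x3 deformation gradient with positive determinant.
#' @param f0 reference fiber direction (unit).
#' @return list with \code{F}, right Cauchy-Green \code{C}, Green-Lagrange
#'   \code{E}, Jacobian \code{J}, fiber stretch \code{alpha}.
#' @export
kinematic_point <- function(F, f0) {
  J <- det(F)
  if (J <= 0) stop("deformation gradient has non-positive Jacobian")
  C <- crossprod(F)
  list(F = F, C = C, E = (C - diag(3)) / 2, J = J,
       alpha = sqrt(drop(t(f0) %*% C %*% f0)))
}

## Q exponent and coefficient array of the bulk law in fiber coordinates
bulk_B <- function(params) {
  matrix(c(params$b_ff, params$b_fs, params$b_fs,
           params$b_fs, params$b_xx, params$b_xx,
           params$b_fs, params$b_xx, params$b_xx), 3, 3, byrow = TRUE)
}

#' Guccione bulk passive stress
#'
#' S = C e^Q (B o E) evaluated in the fiber frame and rotated back to
#' global axes; B holds b_ff on the ff component, b_xx on ss/nn/sn/ns and
#' b_fs on fs/sf/fn/nf.
#'
#' @param E 3x3 Green-Lagrange strain in global axes (symmetric).
#' @param frame \code{fiber_frame}.
#' @param params \code{bulk_params}.
#' @return symmetric 3x3 2nd Piola-Kirchhoff stress (Pa), global axes.
#' @export
bulk_stress <- function(E, frame, params) {
  Q <- unclass(frame)
  Ef <- t(Q) %*% E %*% Q # strain in (f, s, n) coordinates
  B <- bulk_B(params)
  Qexp <- sum(B * Ef^2)
  if (Qexp > 500) stop("bulk strain energy exponent overflow (extreme strain)")
  Sf <- params$C * exp(Qexp) * (B * Ef)
  S <- Q %*% Sf %*% t(Q)
  (S + t(S)) / 2
}

#' Tension-only myofiber passive stress
#'
#' Zero under fiber compression (alpha <= 1); otherwise the rank-1 tensor
#' (Psi'(alpha)/alpha) f0 x f0 with
#' Psi'(alpha) = 2 C_1 C_2 (alpha - 1) e^{C_2 (alpha - 1)^2}.
#'
#' @param point \code{kinematic_point} (uses \code{alpha}).
#' @param frame \code{fiber_frame} (uses the fiber direction).
#' @param params \code{myofiber_params}.
#' @return 3x3 2nd Piola-Kirchhoff stress (Pa).
#' @export
myofiber_passive_stress <- function(point, frame, params) {
  a <- point$alpha
  f0 <- unclass(frame)[, 1]
  if (a <= 1 || params$C_1 == 0) return(matrix(0, 3, 3))
  dpsi <- 2 * params$C_1 * params$C_2 * (a - 1) * exp(params$C_2 * (a - 1)^2)
  (dpsi / a) * tcrossprod(f0)
}

#' Active stress tensor
#'
#' Projects the scalar sarcomere stress along the reference fiber
#' direction: S_a = F_active f0 x f0.
#'
#' @param f_active active fiber stress (Pa).
#' @param f0 unit reference fiber direction.
#' @return 3x3 2nd Piola-Kirchhoff stress.
#' @export
active_stress_tensor <- function(f_active, f0) {
  f_active * tcrossprod(f0 / sqrt(sum(f0^2)))
}

#' Volumetric (incompressibility) stress
#'
#' From Psi_vol = -p (J - 1): S_vol = -p J C^{-1}, where p is the
#' hydrostatic-pressure Lagrange multiplier.
#'
#' @param point \code{kinematic_point}.
#' @param p hydrostatic pressure multiplier (Pa).
#' @return 3x3 2nd Piola-Kirchhoff stress.
#' @export
volumetric_stress <- function(point, p) {
  -p * point$J * solve(point$C)
}

#' Total 2nd Piola-Kirchhoff stress
#'
#' S = S_active + S_vol + S_bulk + S_myofiber — the additive active/passive
#' decomposition used both in the momentum balance and as the driver of the
#' fiber reorientation law.
#'
#' @param point \code{kinematic_point}.
#' @param frame \code{fiber_frame}.
#' @param bulk \code{bulk_params}.
#' @param myo \code{myofiber_params}.
#' @param f_active active fiber stress (Pa).
#' @param p hydrostatic pressure multiplier (Pa).
#' @return symmetric 3x3 stress tensor (Pa).
#' @export
total_stress <- function(point, frame, bulk, myo, f_active = 0, p = 0) {
  active_stress_tensor(f_active, unclass(frame)[, 1]) +
    volumetric_stress(point, p) +
    bulk_stress(point$E, frame, bulk) +
    myofiber_passive_stress(point, frame, myo)
}

#' Regional material table
#'
#' The two material rows used by the disease models: normal myocardium and
#' fibrous (replacement-scar) tissue.  Fibrous tissue is stiffer, isotropic
#' (equal exponents), has no myofiber spring (C_1 = 0) and no contractile
#' machinery (cross-bridge density 0).
#'
#' @return named list with elements \code{normal} and \code{fibrous}, each
#'   holding \code{bulk}, \code{myofiber} and \code{xb_density} (1/m^2).
#' @export
material_table <- function() {
  list(
    normal = list(bulk = bulk_params(C = 200, b_ff = 8, b_xx = 3.58,
                                     b_fs = 1.63),
                  myofiber = myofiber_params(C_1 = 250, C_2 = 15),
                  xb_density = 6.96e16),
    fibrous = list(bulk = bulk_params(C = 2720, b_ff = 4, b_xx = 4,
                                      b_fs = 4),
                   myofiber = myofiber_params(C_1 = 0, C_2 = 0),
                   xb_density = 0)
  )
}
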