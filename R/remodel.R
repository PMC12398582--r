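## Stress-based incremental fiber reorientation.
##
## At each integration point the reference fiber direction relaxes toward
## the local traction direction S f0 / |S f0| with time constant kappa:
## one explicit step blends a dt/kappa fraction of the difference and
## renormalizes.  Fibers are axial (headless) objects, so the traction is
## taken as sign(f0 . S f0) * S f0, which makes the update invariant under
## f0 -> -f0 and prevents rotations beyond 90 degrees.

#' Reorientation parameters
#'
#' @param kappa_ms adaptation time constant (ms, default 4000); the per-step
#'   blending fraction is dt/kappa.
#' @param start_ms simulation time at which reorientation is enabled
#'   (default 5000 ms — the hemodynamic run-in is simulated with fibers
#'   frozen).
#' @param enabled master switch.
#' @return object of class \code{reorientation_params}.
#' @export
reorientation_params <- function(kappa_ms = 4000, start_ms = 5000,
                                 enabled = TRUE) {
  if (kappa_ms <= 0) stop("kappa must be > 0")
  if (start_ms < 0) stop("start time must be >= 0")
  structure(list(kappa_ms = kappa_ms, start_ms = start_ms,
                 enabled = enabled), class = "reorientation_params")
}

#' One reorientation step for a single fiber
#'
#' f0' = normalize(f0 + (dt/kappa) (sigma S f0 / |S f0| - f0)) with
#' sigma = sign(f0 . S f0).  Points with vanishing traction (|S f0| below
#' \code{eps} times the stress scale) are skipped unchanged.
#'
#' @param f0 unit fiber vector.
#' @param S symmetric 3x3 stress tensor (2nd Piola-Kirchhoff).
#' @param dt_ms time step (ms).
#' @param params \code{reorientation_params}.
#' @param eps relative traction threshold for the unloaded-point skip.
#' @return list with \code{f0} (updated unit vector) and \code{skipped}.
#' @export
reorient_step <- function(f0, S, dt_ms, params = reorientation_params(),
                          eps = 1e-12) {
  tr <- drop(S %*% f0)
  nt <- sqrt(sum(tr^2))
  scale <- max(abs(S))
  if (nt <= eps * max(scale, 1e-300)) {
    return(list(f0 = f0, skipped = TRUE))
  }
  sigma <- sign(sum(f0 * tr))
  if (sigma == 0) sigma <- 1
  f <- f0 + (dt_ms / params$kappa_ms) * (sigma * tr / nt - f0)
  list(f0 = f / sqrt(sum(f^2)), skipped = FALSE)
}

#' Rebuild an orthonormal frame around an updated fiber direction
#'
#' The sheet vector keeps its previous orientation projected off the new
#' fiber direction (continuous in f0'); the sheet-normal closes the
#' right-handed triad.
#'
#' @param f0_new updated unit fiber vector.
#' @param frame previous frame: list/matrix with \code{s0}, \code{n0}.
#' @return list with \code{f0}, \code{s0}, \code{n0}.
#' @export
rebuild_frame <- function(f0_new, frame) {
  s0 <- frame$s0 - sum(frame$s0 * f0_new) * f0_new
  ns <- sqrt(sum(s0^2))
  if (ns < 1e-8) { # fallback when the old sheet collapsed onto f0'
    s0 <- frame$n0 - sum(frame$n0 * f0_new) * f0_new
    ns <- sqrt(sum(s0^2))
  }
  s0 <- s0 / ns
  n0 <- cross3(f0_new, s0)
  list(f0 = f0_new, s0 = s0, n0 = n0)
}

#' Vectorized reorientation update over all quadrature points
#'
#' Applies \code{\link{reorient_step}} + \code{\link{rebuild_frame}} at
#' every quadrature point using the total-stress field of the converged
#' step, and tracks the cumulative 3D reorientation angle from the initial
#' fiber field (axial convention).
#'
#' @param frames list with matrices \code{f0}, \code{s0}, \code{n0}
#'   (n_qp x 3), and optionally \code{f0_init}.
#' @param S_voigt n_qp x 6 total stress (order 11, 22, 33, 23, 13, 12).
#' @param dt_ms time step (ms).
#' @param params \code{reorientation_params}.
#' @param eps traction threshold, as in \code{reorient_step}.
#' @return updated frames (with \code{f0_init} retained and \code{skips}
#'   count attached).
#' @export
reorientation_field_update <- function(frames, S_voigt, dt_ms,
                                       params = reorientation_params(),
                                       eps = 1e-12) {
  f0 <- frames$f0
  if (is.null(frames$f0_init)) frames$f0_init <- f0
  ## traction t = S f0 from Voigt components
  tx <- S_voigt[, 1] * f0[, 1] + S_voigt[, 6] * f0[, 2] + S_voigt[, 5] * f0[, 3]
  ty <- S_voigt[, 6] * f0[, 1] + S_voigt[, 2] * f0[, 2] + S_voigt[, 4] * f0[, 3]
  tz <- S_voigt[, 5] * f0[, 1] + S_voigt[, 4] * f0[, 2] + S_voigt[, 3] * f0[, 3]
  nt <- sqrt(tx^2 + ty^2 + tz^2)
  scale <- max(abs(S_voigt))
  active <- nt > eps * max(scale, 1e-300)
  sigma <- sign(tx * f0[, 1] + ty * f0[, 2] + tz * f0[, 3])
  sigma[sigma == 0] <- 1
  lam <- dt_ms / params$kappa_ms
  f <- f0
  a <- active
  f[a, 1] <- f0[a, 1] + lam * (sigma[a] * tx[a] / nt[a] - f0[a, 1])
  f[a, 2] <- f0[a, 2] + lam * (sigma[a] * ty[a] / nt[a] - f0[a, 2])
  f[a, 3] <- f0[a, 3] + lam * (sigma[a] * tz[a] / nt[a] - f0[a, 3])
  f <- normalize_rows(f)
  ## rebuild sheet/normal
  s0 <- frames$s0 - rowSums(frames$s0 * f) * f
  ns <- sqrt(rowSums(s0^2))
  bad <- ns < 1e-8
  if (any(bad)) {
    s0[bad, ] <- frames$n0[bad, , drop = FALSE] -
      rowSums(frames$n0[bad, , drop = FALSE] * f[bad, , drop = FALSE]) *
      f[bad, , drop = FALSE]
    ns[bad] <- sqrt(rowSums(s0[bad, , drop = FALSE]^2))
  }
  s0 <- s0 / ns
  n0 <- cbind(f[, 2] * s0[, 3] - f[, 3] * s0[, 2],
              f[, 3] * s0[, 1] - f[, 1] * s0[, 3],
              f[, 1] * s0[, 2] - f[, 2] * s0[, 1])
  frames$f0 <- f
  frames$s0 <- s0
  frames$n0 <- n0
  frames$skips <- sum(!active)
  frames
}

#' Cumulative reorientation angle from the initial fiber field
#'
#' @param frames frames list carrying \code{f0} and \code{f0_init}.
#' @return angle per quadrature point in degrees, in [0, 90].
#' @export
cumulative_reorientation_angle <- function(frames) {
  if (is.null(frames$f0_init)) return(rep(0, nrow(frames$f0)))
  reorientation_angle(frames$f0_init, frames$f0)
}
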