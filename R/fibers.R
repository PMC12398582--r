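## Rule-based myofiber architecture on the ellipsoidal wall.
##
## The local wall basis (circumferential, longitudinal, radial) is built
## from the gradient of the transmural coordinate field and the long axis;
## the helix angle varies linearly across the wall and the transverse angle
## is constant (default zero).  The chart is singular on the long axis at
## the apex: quadrature points inside a small polar cap inherit the basis
## of the nearest well-defined point.

#' Fiber rule specification
#'
#' @param endo_deg helix angle at the endocardium (degrees, default +60).
#' @param epi_deg helix angle at the epicardium (degrees, default -60).
#' @param transverse_deg constant transverse angle (degrees, default 0).
#' @return object of class \code{fiber_rule}.
#' @export
fiber_rule <- function(endo_deg = 60, epi_deg = -60, transverse_deg = 0) {
  ang <- c(endo_deg, epi_deg, transverse_deg)
  if (any(ang <= -90 | ang > 90)) stop("angles must lie in (-90, 90]")
  structure(list(endo_deg = endo_deg, epi_deg = epi_deg,
                 transverse_deg = transverse_deg), class = "fiber_rule")
}

#' Helix angle of the linear transmural rule
#'
#' @param t transmural coordinate in [0, 1] (0 = endo).
#' @param rule \code{fiber_rule}.
#' @return helix angle in degrees.
#' @export
helix_angle_rule <- function(t, rule = fiber_rule()) {
  rule$endo_deg + (rule$epi_deg - rule$endo_deg) * t
}

normalize_rows <- function(m) m / sqrt(rowSums(m^2))

## local wall basis at every quadrature point; returns circumferential,
## longitudinal (toward base), radial (endo->epi) unit vectors and the
## degenerate-cap mask
wall_basis <- function(fe) {
  mesh <- fe$mesh
  nqp <- fe$n_qp
  nq <- fe$nq
  gradt <- matrix(0, nqp, 3)
  for (e in seq_len(nrow(mesh$elems))) {
    conn <- mesh$elems[e, ]
    te <- mesh$t_node[conn]
    for (q in seq_len(nq)) {
      iq <- (e - 1L) * nq + q
      gradt[iq, ] <- te %*% fe$dNg[, , iq]
    }
  }
  er <- normalize_rows(gradt)
  zxer <- cbind(-er[, 2], er[, 1], 0)
  sin_pol <- sqrt(rowSums(zxer^2))
  degen <- sin_pol < 0.05
  ec <- zxer / pmax(sin_pol, 1e-30)
  if (any(degen)) {
    good <- which(!degen)
    pos <- fe$pos
    for (iq in which(degen)) {
      d2 <- rowSums((pos[good, , drop = FALSE] -
                       matrix(pos[iq, ], length(good), 3, byrow = TRUE))^2)
      j <- good[which.min(d2)]
      er[iq, ] <- er[j, ]
      ec[iq, ] <- ec[j, ]
    }
  }
  ## re-orthonormalize after inheritance
  el <- cbind(er[, 2] * ec[, 3] - er[, 3] * ec[, 2],
              er[, 3] * ec[, 1] - er[, 1] * ec[, 3],
              er[, 1] * ec[, 2] - er[, 2] * ec[, 1])
  el <- normalize_rows(el)
  ec <- cbind(el[, 2] * er[, 3] - el[, 3] * er[, 2],
              el[, 3] * er[, 1] - el[, 1] * er[, 3],
              el[, 1] * er[, 2] - el[, 2] * er[, 1])
  ec <- normalize_rows(ec)
  list(ec = ec, el = el, er = er, degenerate = degen)
}

#' Assign rule-based fiber frames at quadrature points
#'
#' Builds the orthonormal (fiber, sheet, sheet-normal) triad at every
#' quadrature point from the linear transmural helix-angle rule applied in
#' the local wall basis; the sheet direction is radial.
#'
#' @param fe \code{lv_fe}.
#' @param rule \code{fiber_rule}.
#' @return list with \code{f0}, \code{s0}, \code{n0} (n_qp x 3), the wall
#'   \code{basis}, helix/transverse rule values and the degenerate mask.
#' @export
assign_rule_based_fibers <- function(fe, rule = fiber_rule()) {
  basis <- wall_basis(fe)
  hel <- helix_angle_rule(fe$t_qp, rule) * pi / 180
  trv <- rule$transverse_deg * pi / 180
  f0 <- cos(trv) * (cos(hel) * basis$ec + sin(hel) * basis$el) +
    sin(trv) * basis$er
  f0 <- normalize_rows(f0)
  s0 <- basis$er - rowSums(basis$er * f0) * f0
  s0 <- normalize_rows(s0)
  n0 <- cbind(f0[, 2] * s0[, 3] - f0[, 3] * s0[, 2],
              f0[, 3] * s0[, 1] - f0[, 1] * s0[, 3],
              f0[, 1] * s0[, 2] - f0[, 2] * s0[, 1])
  list(f0 = f0, s0 = s0, n0 = n0, basis = basis,
       helix_deg = hel * 180 / pi, degenerate = basis$degenerate)
}
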