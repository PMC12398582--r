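## Postprocessing: pressure-volume metrics, fiber-angle and disarray
## measures, systolic strain, and cross-distribution variability.

#' Pressure-volume metrics of a cardiac cycle
#'
#' EDV is the maximum and ESV the minimum cavity volume within the cycle;
#' SV = EDV - ESV and EF = SV/EDV.  By default metrics are reported for the
#' last complete cycle of the trace.
#'
#' @param time_s time stamps (s).
#' @param volume_ml cavity volume (mL).
#' @param pressure_mmhg cavity pressure (mmHg).
#' @param period_s cycle period (s).
#' @param cycle which cycle (default last complete).
#' @return list with \code{EDV_ml}, \code{ESV_ml}, \code{SV_ml},
#'   \code{EF_pct}, \code{peak_pressure_mmhg}, and the ED/ES times.
#' @export
pv_metrics <- function(time_s, volume_ml, pressure_mmhg, period_s,
                       cycle = NULL) {
  ncyc <- floor((max(time_s) + 1e-9) / period_s)
  if (ncyc < 1) stop("trace shorter than one cycle")
  if (is.null(cycle)) cycle <- ncyc
  sel <- time_s > (cycle - 1) * period_s - 1e-9 &
    time_s <= cycle * period_s + 1e-9
  if (!any(sel)) stop("no samples in the requested cycle")
  v <- volume_ml[sel]; p <- pressure_mmhg[sel]; tt <- time_s[sel]
  i_ed <- which.max(v); i_es <- which.min(v)
  edv <- v[i_ed]; esv <- v[i_es]
  list(EDV_ml = edv, ESV_ml = esv, SV_ml = edv - esv,
       EF_pct = 100 * (edv - esv) / edv,
       peak_pressure_mmhg = max(p),
       t_ed = tt[i_ed], t_es = tt[i_es])
}

#' 3D reorientation angle between fiber fields
#'
#' Axial (sign-free) convention: theta = acos(|f_init . f_final|), in
#' [0, 90] degrees — fibers are directionless, so f and -f are the same
#' fiber.
#'
#' @param f_init,f_final unit vectors (length 3) or n x 3 matrices.
#' @return angle(s) in degrees.
#' @export
reorientation_angle <- function(f_init, f_final) {
  a <- rbind(f_init); b <- rbind(f_final)
  d <- abs(rowSums(a * b))
  acos(pmin(1, d)) * 180 / pi
}

#' Helical and transverse fiber angles in the local wall basis
#'
#' helix = atan2(f . l, f . c) folded to [-90, 90]; transverse =
#' asin(f . r), with (c, l, r) the circumferential/longitudinal/radial
#' unit vectors.
#'
#' @param f0 n x 3 fiber vectors.
#' @param basis list with \code{ec}, \code{el}, \code{er} (n x 3).
#' @return data.frame with \code{helix_deg}, \code{transverse_deg}.
#' @export
helix_transverse_angles <- function(f0, basis) {
  f0 <- rbind(f0)
  fc <- rowSums(f0 * basis$ec)
  fl <- rowSums(f0 * basis$el)
  fr <- rowSums(f0 * basis$er)
  helix <- atan2(fl, fc) * 180 / pi
  ## fold to (-90, 90]: fibers are axial
  helix <- ifelse(helix > 90, helix - 180, helix)
  helix <- ifelse(helix <= -90, helix + 180, helix)
  transverse <- asin(pmax(-1, pmin(1, fr))) * 180 / pi
  data.frame(helix_deg = helix, transverse_deg = transverse)
}

#' Angular deviation within a transmural layer
#'
#' The (quadrature-weighted, sample-convention) standard deviation of an
#' angle field over the epicardial (t >= 0.8) or endocardial (t <= 0.2)
#' layer — each layer spans 20% of the transmural thickness.
#'
#' @param angles_deg angle per quadrature point (degrees).
#' @param t_qp transmural coordinate per point.
#' @param layer "epi" or "endo".
#' @param weights quadrature weights (optional; unweighted if NULL).
#' @param exclude logical mask of points to drop (e.g. the apex cap).
#' @return angular deviation in degrees.
#' @export
angular_deviation <- function(angles_deg, t_qp, layer = c("epi", "endo"),
                              weights = NULL, exclude = NULL) {
  layer <- match.arg(layer)
  sel <- if (layer == "epi") t_qp >= 0.8 else t_qp <= 0.2
  if (!is.null(exclude)) sel <- sel & !exclude
  if (!any(sel)) stop("empty ", layer, " layer")
  a <- angles_deg[sel]
  if (is.null(weights)) {
    stats::sd(a)
  } else {
    w <- weights[sel] / sum(weights[sel])
    mu <- sum(w * a)
    n_eff <- 1 / sum(w^2)
    sqrt(sum(w * (a - mu)^2) * n_eff / (n_eff - 1))
  }
}

#' Systolic strain from end-diastolic and end-systolic deformation
#'
#' Multiplicative decomposition F_sys = F_ES F_ED^{-1}; the Lagrangian
#' strain relative to end-diastole E = (F_sys^T F_sys - I)/2 is projected
#' on the longitudinal, circumferential and radial directions and reported
#' in percent.
#'
#' @param F_ed,F_es 3x3 deformation gradients at the same material point.
#' @param basis list with unit vectors \code{ec}, \code{el}, \code{er}
#'   (length-3 each).
#' @return named numeric: longitudinal, circumferential, radial strain (%).
#' @export
systolic_strain <- function(F_ed, F_es, basis) {
  Fsys <- F_es %*% solve(F_ed)
  E <- (crossprod(Fsys) - diag(3)) / 2
  proj <- function(v) drop(t(v) %*% E %*% v)
  100 * c(longitudinal = proj(basis$el), circumferential = proj(basis$ec),
          radial = proj(basis$er))
}

#' Coefficient of variation of a metric across distribution variants
#'
#' CV = 100 * sd/mean (sample sd), e.g. of a layer angular deviation across
#' the three focus-size distributions.
#'
#' @param values numeric vector (>= 2 values).
#' @return CV in percent.
#' @export
cv_across_distributions <- function(values) {
  if (length(values) < 2) stop("need at least two variants")
  m <- mean(values)
  if (m == 0) stop("zero mean: CV undefined")
  100 * stats::sd(values) / m
}
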