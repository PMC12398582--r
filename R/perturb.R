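## Heterogeneous HCM perturbation fields.
##
## Spherical foci with a minimum diameter are seeded uniformly in the wall
## (no transmural preference) and accepted until the quadrature-weighted
## perturbed volume fraction reaches the target (30% by default).  The
## perturbed points then receive either a scaled SRX->DRX recruitment rate
## k_1 (hyper/hypocontractile) or the fibrous material row (stiffer,
## isotropic, non-contractile).

#' Perturbation specification
#'
#' @param type one of "baseline", "hypercontractile", "hypocontractile",
#'   "fibrous".
#' @param fraction target perturbed volume fraction (default 0.30).
#' @param min_size_mm minimum focus diameter in mm; the presets 3.0 / 2.5 /
#'   2.0 correspond to Distributions 1-3.
#' @param k1_scale magnitude of the k_1 scaling for the contractility
#'   models (0.2, 0.6 or 1.0 = 20/60/100%); sign is taken from \code{type}.
#' @param seed RNG seed making the labels a pure function of
#'   (mesh, spec, seed).
#' @return object of class \code{perturbation_spec}.
#' @export
perturbation_spec <- function(type = c("baseline", "hypercontractile",
                                       "hypocontractile", "fibrous"),
                              fraction = 0.30, min_size_mm = 3.0,
                              k1_scale = 1.0, seed = 1L) {
  type <- match.arg(type)
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  if (min_size_mm <= 0) stop("minimum focus size must be > 0")
  if (k1_scale < 0 || k1_scale > 1) stop("k1_scale must lie in [0, 1]")
  structure(list(type = type, fraction = fraction,
                 min_size_mm = min_size_mm, k1_scale = k1_scale,
                 seed = as.integer(seed)), class = "perturbation_spec")
}

#' Generate perturbed-region labels on the quadrature points
#'
#' Rejection-samples focus centres uniformly in the wall volume (candidate
#' centres drawn from quadrature points weighted by their volume weights,
#' with a jitter of half the local point spacing), draws focus radii
#' uniformly in [min/2, 1.5 min/2], and accepts foci until the realized
#' quadrature-weighted fraction is within the tolerance band of the
#' target.  Deterministic given (mesh, spec, seed).
#'
#' @param fe \code{lv_fe}.
#' @param spec \code{perturbation_spec}.
#' @param tol acceptance half-band on the realized fraction (default 0.02).
#' @return object of class \code{region_labels}: logical
#'   \code{perturbed} per quadrature point, the realized fraction, the
#'   focus inventory and the material tag.
#' @export
generate_regions <- function(fe, spec, tol = 0.02) {
  nqp <- fe$n_qp
  labels <- list(perturbed = rep(FALSE, nqp), fraction = 0,
                 foci = data.frame(), spec = spec,
                 material = if (spec$type == "fibrous") "fibrous" else "normal")
  class(labels) <- "region_labels"
  if (spec$type == "baseline" || spec$fraction == 0) return(labels)

  wtot <- sum(fe$wdet)
  rmin <- spec$min_size_mm / 2 * 1e-3
  set.seed(spec$seed)
  perturbed <- rep(FALSE, nqp)
  centres <- list()
  frac <- 0
  guard <- 0
  jitter_sd <- rmin / 2
  while (frac < spec$fraction - tol && guard < 20000) {
    guard <- guard + 1
    idx <- sample.int(nqp, 1, prob = fe$wdet)
    ctr <- fe$pos[idx, ] + rnorm(3, sd = jitter_sd)
    r <- runif(1, rmin, 1.5 * rmin)
    d2 <- (fe$pos[, 1] - ctr[1])^2 + (fe$pos[, 2] - ctr[2])^2 +
      (fe$pos[, 3] - ctr[3])^2
    inside <- d2 <= r^2
    cand <- perturbed | inside
    f2 <- sum(fe$wdet[cand]) / wtot
    if (f2 > spec$fraction + tol) next # would overshoot: redraw
    if (any(inside & !perturbed)) {
      perturbed <- cand
      frac <- f2
      centres[[length(centres) + 1]] <- c(ctr, r)
    }
  }
  if (frac < spec$fraction - tol)
    stop("could not reach the target perturbed fraction (packing error: ",
         "focus size too large for the wall?)")
  labels$perturbed <- perturbed
  labels$fraction <- frac
  if (length(centres))
    labels$foci <- as.data.frame(do.call(rbind, centres)) |>
      stats::setNames(c("x", "y", "z", "radius"))
  labels
}

#' Per-point k_1 field for a contractility perturbation
#'
#' Perturbed points receive k_1 (1 + s) with s = +k1_scale for
#' hypercontractile and -k1_scale for hypocontractile models; normal points
#' keep the base value.  s = -1 fully suppresses SRX->DRX recruitment.
#'
#' @param labels \code{region_labels}.
#' @param k1_base baseline k_1 (1/s).
#' @param spec \code{perturbation_spec} (defaults to the one in
#'   \code{labels}).
#' @return numeric k_1 per quadrature point.
#' @export
apply_contractility <- function(labels, k1_base, spec = labels$spec) {
  s <- switch(spec$type,
              hypercontractile = spec$k1_scale,
              hypocontractile = -spec$k1_scale,
              0)
  k1 <- rep(k1_base, length(labels$perturbed))
  k1[labels$perturbed] <- k1_base * (1 + s)
  k1
}

#' Per-point material assignment for the fibrous perturbation
#'
#' @param fe \code{lv_fe}.
#' @param labels \code{region_labels}; for \code{type = "fibrous"} the
#'   perturbed points get the fibrous row of \code{\link{material_table}}
#'   (no myofiber spring, no active stress), all others the normal row.
#' @param table material table.
#' @return per-quadrature-point material arrays as in
#'   \code{\link{qp_materials}}.
#' @export
apply_fibrous <- function(fe, labels, table = material_table()) {
  if (labels$spec$type != "fibrous") return(qp_materials(fe, table = table))
  qp_materials(fe, labels = labels, table = table)
}
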