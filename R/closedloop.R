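## Closed-loop multiscale simulation driver.
##
## Staggered coupling, once per global time step:
##   calcium transient -> cross-bridge ODEs (using strain and total fiber
##   stress from the previous converged step) -> circulation volume update
##   (using the previous cavity pressure) -> quasi-static mechanics solve
##   at the new target cavity volume -> (after the run-in) stress-driven
##   fiber reorientation using the converged total-stress field.
##
## Protocol: rule-based fiber initialization; a hemodynamic run-in with
## fibers frozen; fiber remodeling for the remainder of the run.

#' Run the closed-loop LV simulation
#'
#' @param config configuration from \code{\link{default_config}}; fields
#'   can be overridden via \code{...} (e.g. \code{protocol =
#'   list(n_cycles = 4)} is merged into the default protocol).
#' @param ... named overrides merged into \code{config}.
#' @param record_fields if TRUE, keep end-diastolic/end-systolic
#'   deformation gradients of the last cycle (for strain maps).
#' @param verbose print per-cycle summaries.
#' @return object of class \code{lv_run}: per-step hemodynamic series,
#'   per-cycle metrics, final/initial fiber frames, region labels, the FE
#'   workspace and final mechanics state.
#' @export
run_closed_loop <- function(config = default_config(), ...,
                            record_fields = TRUE, verbose = FALSE) {
  dots <- list(...)
  for (nm in names(dots)) {
    config[[nm]] <- if (is.list(config[[nm]]) && is.list(dots[[nm]]) &&
                        !inherits(config[[nm]], c("circ_params")))
      modifyList(config[[nm]], dots[[nm]]) else dots[[nm]]
  }
  proto <- config$protocol
  dt_s <- proto$dt_ms * lv_units$ms
  period_s <- proto$period_ms * lv_units$ms
  steps_per_cycle <- round(proto$period_ms / proto$dt_ms)
  if (abs(steps_per_cycle * proto$dt_ms - proto$period_ms) > 1e-6)
    stop("dt must divide the cycle period")
  n_steps <- steps_per_cycle * proto$n_cycles

  ## ---- spatial setup ----
  mesh <- build_ellipsoid_mesh(config$geometry, config$resolution)
  fe <- fe_setup(mesh)
  frames <- assign_rule_based_fibers(fe, config$fiber_rule)
  frames$f0_init <- frames$f0
  basis0 <- frames$basis
  labels <- generate_regions(fe, config$perturbation)
  mats <- if (labels$spec$type == "fibrous")
    apply_fibrous(fe, labels, config$materials)
  else qp_materials(fe, table = config$materials)
  k1_qp <- apply_contractility(labels, config$sarcomere$k_1)

  ## ---- state ----
  xb <- xb_state_init(config$sarcomere, fe$n_qp)
  capar <- config$calcium
  capar$period <- period_s
  circ <- circulation_init(config$circulation, config$initial_pressures,
                           v_lv = cavity_volume(fe))
  st <- mechanics_state_init(fe)
  cache <- new.env(parent = emptyenv())
  st <- solve_mechanics_step(fe, frames, mats, numeric(fe$n_qp), st,
                             cavity_volume(fe), config$newton, cache)
  alpha_prev <- st$fields$alpha
  sff_prev <- pmax(0, st$fields$Sff_myo) # + zero active at rest
  sact_prev <- numeric(fe$n_qp)
  u_prev <- st$u

  series <- data.frame(t_ms = numeric(n_steps), V_lv_ml = numeric(n_steps),
                       P_lv_mmhg = numeric(n_steps),
                       P_aorta_mmhg = numeric(n_steps),
                       P_veins_mmhg = numeric(n_steps),
                       Q_out_ml_s = numeric(n_steps),
                       Q_in_ml_s = numeric(n_steps),
                       total_volume_ml = numeric(n_steps))
  hsl_ref <- config$sarcomere$hsl_ref
  xb_scale <- mats$xb_scale

  F_ed <- F_es <- NULL
  v_ed <- -Inf; v_es <- Inf
  last_cycle_start <- (proto$n_cycles - 1) * steps_per_cycle

  for (istep in seq_len(n_steps)) {
    t_now <- istep * dt_s
    ## 1. calcium + cross-bridge kinetics (strain feedback from the
    ##    previous converged mechanics step)
    ca <- calcium_transient(t_now, capar)
    f_total <- pmax(0, sff_prev + sact_prev)
    dhsl <- hsl_ref * (st$fields$alpha - alpha_prev)
    alpha_prev <- st$fields$alpha
    xb <- step_states(xb, ca, f_total, dhsl, config$sarcomere, dt_s,
                      k1 = k1_qp)
    sact <- active_force(xb, config$sarcomere) * xb_scale

    ## 2. circulation explicit update with the previous cavity pressure
    pr <- compartment_pressures(circ, config$circulation)
    pr <- c(pr, ventricle = unname(st$plv))
    q <- circulation_flows(pr, config$circulation)
    circ <- step_volumes(circ, q, dt_s)
    v_target <- unname(unclass(circ)[["ventricle"]])

    ## 3. mechanics at the new target volume (with displacement predictor
    ##    and load continuation as fallback)
    st_try <- st
    st_try$u <- st$u + (st$u - u_prev)
    v_prev <- st$V
    u_prev <- st$u
    visc <- list(gamma = config$newton$damping / dt_s, u_ref = st$u)
    st <- tryCatch(
      solve_mechanics_step(fe, frames, mats, sact, st_try, v_target,
                           config$newton, cache, visc),
      error = function(e)
        solve_mechanics_ramp(fe, frames, mats, sact_prev, sact,
                             v_prev, v_target, st, config$newton,
                             cache = cache, visc = visc))
    sff_prev <- st$fields$Sff_myo
    sact_prev <- sact

    ## 4. fiber reorientation (after the run-in)
    if (config$remodeling$enabled &&
        t_now >= config$remodeling$start_ms * lv_units$ms) {
      frames <- reorientation_field_update(frames, st$fields$S,
                                           proto$dt_ms, config$remodeling)
    }

    series[istep, ] <- c(t_now / lv_units$ms, st$V / lv_units$mL,
                         convert_pressure(st$plv, "mmHg"),
                         convert_pressure(pr[["aorta"]], "mmHg"),
                         convert_pressure(pr[["veins"]], "mmHg"),
                         q[["aorta"]] / lv_units$mL,
                         q[["ventricle"]] / lv_units$mL,
                         sum(unclass(circ)) / lv_units$mL)

    if (record_fields && istep > last_cycle_start) {
      if (st$V > v_ed) { v_ed <- st$V; F_ed <- st$fields$F }
      if (st$V < v_es) { v_es <- st$V; F_es <- st$fields$F }
    }
    if (verbose && istep %% steps_per_cycle == 0) {
      cyc <- istep / steps_per_cycle
      pm <- pv_metrics(series$t_ms[1:istep] / 1000, series$V_lv_ml[1:istep],
                       series$P_lv_mmhg[1:istep], period_s, cycle = cyc)
      message(sprintf("cycle %d: EDV %.1f ESV %.1f EF %.1f%% peakP %.1f",
                      cyc, pm$EDV_ml, pm$ESV_ml, pm$EF_pct,
                      pm$peak_pressure_mmhg))
    }
  }

  cycles <- do.call(rbind, lapply(seq_len(proto$n_cycles), function(cy) {
    pm <- pv_metrics(series$t_ms / 1000, series$V_lv_ml, series$P_lv_mmhg,
                     period_s, cycle = cy)
    data.frame(cycle = cy, EDV_ml = pm$EDV_ml, ESV_ml = pm$ESV_ml,
               SV_ml = pm$SV_ml, EF_pct = pm$EF_pct,
               peak_P_mmhg = pm$peak_pressure_mmhg)
  }))

  structure(list(config = config, mesh = mesh, fe = fe,
                 frames = frames, basis = basis0, labels = labels,
                 series = series, cycles = cycles,
                 F_ed = F_ed, F_es = F_es,
                 state = st, xb = xb, circulation = circ),
            class = "lv_run")
}

#' @export
print.lv_run <- function(x, ...) {
  n <- nrow(x$cycles)
  cat("Closed-loop LV run:", n, "cycles,",
      x$config$perturbation$type, "model\n")
  print(utils::tail(x$cycles, 3), row.names = FALSE)
  invisible(x)
}

#' Disarray metrics of a completed run
#'
#' Helical/transverse angular deviations in the epicardial and endocardial
#' layers (20% transmural thickness each) of the final fiber field, plus
#' the mean cumulative reorientation angle.  Apex-cap points with a
#' degenerate wall basis are excluded.
#'
#' @param run \code{lv_run}.
#' @return list with helical/transverse AD per layer (degrees) and the
#'   mean/max reorientation angle.
#' @export
disarray_metrics <- function(run) {
  ang <- helix_transverse_angles(run$frames$f0, run$basis)
  excl <- run$frames$degenerate
  w <- run$fe$wdet
  t_qp <- run$fe$t_qp
  reo <- cumulative_reorientation_angle(run$frames)
  list(
    helical_AD_epi = angular_deviation(ang$helix_deg, t_qp, "epi", w, excl),
    helical_AD_endo = angular_deviation(ang$helix_deg, t_qp, "endo", w, excl),
    transverse_AD_epi = angular_deviation(ang$transverse_deg, t_qp, "epi",
                                          w, excl),
    transverse_AD_endo = angular_deviation(ang$transverse_deg, t_qp, "endo",
                                           w, excl),
    mean_reorientation_deg = sum(w * reo) / sum(w),
    max_reorientation_deg = max(reo))
}

#' Systolic strain field of a completed run
#'
#' Lagrangian strain of end-systole relative to end-diastole at every
#' quadrature point, projected on the local wall directions.
#'
#' @param run \code{lv_run} (with \code{record_fields = TRUE}).
#' @return data.frame with longitudinal/circumferential/radial strain (%)
#'   per quadrature point plus the transmural coordinate.
#' @export
systolic_strain_field <- function(run) {
  if (is.null(run$F_ed) || is.null(run$F_es))
    stop("run was made without record_fields = TRUE")
  nqp <- nrow(run$F_ed)
  out <- matrix(NA_real_, nqp, 3)
  for (iq in seq_len(nqp)) {
    Fed <- matrix(run$F_ed[iq, ], 3, 3, byrow = TRUE)
    Fes <- matrix(run$F_es[iq, ], 3, 3, byrow = TRUE)
    b <- list(ec = run$basis$ec[iq, ], el = run$basis$el[iq, ],
              er = run$basis$er[iq, ])
    out[iq, ] <- systolic_strain(Fed, Fes, b)
  }
  data.frame(longitudinal = out[, 1], circumferential = out[, 2],
             radial = out[, 3], t = run$fe$t_qp)
}
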