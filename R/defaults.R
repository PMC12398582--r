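## Default model parameters.
##
## The material table, geometry, fiber rule, pacing period, time step,
## remodeling constant and perturbation presets follow the published study
## conditions.  The circulation R/C/slack values and the sarcomere rate
## constants are package defaults chosen once so that the baseline model
## reproduces a healthy adult operating point (total blood volume 4.5 L,
## EDV ~123 mL, ESV ~54 mL, EF ~56%, arterial pressure ~120/80 mmHg); see
## the methods vignette for the calibration rationale.

#' Default circulation parameters
#'
#' Seven-compartment systemic loop in clinical units internally converted
#' to SI.  Resistances are named after the compartment the flow enters
#' (aorta = aortic valve, ventricle = mitral inflow).
#'
#' @param total_volume_ml total blood volume (mL, default 4500).
#' @return \code{circ_params}.
#' @export
default_circulation_params <- function(total_volume_ml = 4500) {
  r_mmhg_s_ml <- c(aorta = 0.030, arteries = 0.050, arterioles = 0.700,
                   capillaries = 0.300, venules = 0.080, veins = 0.020,
                   ventricle = 0.015)
  c_ml_mmhg <- c(aorta = 0.5, arteries = 1.2, arterioles = 0.1,
                 capillaries = 0.3, venules = 8, veins = 60)
  slack_ml <- c(aorta = 60, arteries = 200, arterioles = 80,
                capillaries = 250, venules = 400, veins = 2848)
  circulation_params(
    resistances = r_mmhg_s_ml * lv_units$mmHg / lv_units$mL,
    compliances = c_ml_mmhg * lv_units$mL / lv_units$mmHg,
    slack_volumes = slack_ml * lv_units$mL,
    total_volume = total_volume_ml * lv_units$mL)
}

#' Default diastolic operating point for circulation initialization
#'
#' @return named pressures (Pa) for the six non-LV compartments.
#' @export
default_initial_pressures <- function() {
  c(aorta = 80, arteries = 78, arterioles = 50, capillaries = 20,
    venules = 8, veins = 6.6) * lv_units$mmHg
}

#' Default full run configuration
#'
#' Nested configuration of every module with the baseline (healthy) model.
#' Fields can be overridden via \code{modifyList} or the \code{...}
#' arguments of \code{\link{run_closed_loop}}.
#'
#' @param resolution mesh resolution preset (default "coarse").
#' @return nested list of class \code{lv_config}.
#' @export
default_config <- function(resolution = "coarse") {
  structure(list(
    geometry = lv_geometry(),
    resolution = resolution,
    fiber_rule = fiber_rule(),
    materials = material_table(),
    circulation = default_circulation_params(),
    initial_pressures = default_initial_pressures(),
    sarcomere = xb_params(),
    calcium = calcium_params(stim_offset = 0.4),
    remodeling = reorientation_params(),
    perturbation = perturbation_spec("baseline"),
    protocol = list(period_ms = 937, dt_ms = 1, n_cycles = 8,
                    remodel_start_ms = 5000),
    newton = list(rtol = 1e-4, atol = 1e-10, maxit = 40,
                  vol_tol = 1e-3 * lv_units$mL,
                  damping = 1e5)
  ), class = "lv_config")
}
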