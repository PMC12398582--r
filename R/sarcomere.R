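## Half-sarcomere contraction model: thin-filament activation plus myosin
## SRX/DRX/force-generating kinetics resolved on a cross-bridge strain grid
## of 21 bins at 1 nm spacing over -10..10 nm.  25 ODEs per integration
## point: N_off, N_on, M_SRX, M_DRX and M_FG over the bins.

XB_NBIN <- 21L
XB_GRID <- seq(-10, 10, by = 1) # nm

#' Cross-bridge model parameters
#'
#' Rate constants and mechanical constants of the half-sarcomere model.
#' Units: \code{k_on} 1/(M s); \code{k_off}, \code{k_1}, \code{k_2},
#' \code{k_3}, \code{k_4_0} 1/s; \code{k_coop} dimensionless;
#' \code{k_force} 1/Pa; \code{k_4_1} 1/(s nm^4); \code{k_cb} N/m;
#' \code{kBT} J; \code{x_ps} nm; \code{N_0} 1/m^2 (areal density of myosin
#' heads).  The strain grid is fixed at 21 bins, -10..10 nm.
#'
#' @param k_on,k_off,k_coop thin-filament on/off rates and cooperativity.
#' @param k_1,k_force,k_2 SRX<->DRX rates; \code{k_1} is scaled regionally
#'   in the hyper/hypocontractile disease models.
#' @param k_3,k_4_0,k_4_1 attachment rate and (strain-dependent) detachment.
#' @param k_cb cross-bridge link stiffness.
#' @param kBT thermal energy (default body temperature, 310 K).
#' @param x_ps power-stroke distance.
#' @param N_0 myosin head density; \code{N_0 * k_cb * x} has units of Pa.
#' @param hsl_ref reference half-sarcomere length (nm) linking continuum
#'   fiber stretch alpha to sarcomere kinematics via hsl = hsl_ref * alpha.
#' @param dt_sub integrator sub-step (s) within a global time step.
#' @return object of class \code{xb_params}.
#' @export
xb_params <- function(k_on = 2e8, k_off = 75, k_coop = 5,
                      k_1 = 3.7, k_force = 2e-4, k_2 = 200,
                      k_3 = 43, k_4_0 = 100, k_4_1 = 0.055,
                      k_cb = 0.001, kBT = 1.380649e-23 * 310,
                      x_ps = 5, N_0 = 6.96e16,
                      hsl_ref = 950, dt_sub = 1e-4) {
  p <- list(k_on = k_on, k_off = k_off, k_coop = k_coop, k_1 = k_1,
            k_force = k_force, k_2 = k_2, k_3 = k_3, k_4_0 = k_4_0,
            k_4_1 = k_4_1, k_cb = k_cb, kBT = kBT, x_ps = x_ps, N_0 = N_0,
            hsl_ref = hsl_ref, dt_sub = dt_sub)
  rates <- p[c("k_on", "k_off", "k_coop", "k_1", "k_force", "k_2", "k_3",
               "k_4_0", "k_4_1")]
  if (any(unlist(rates) < 0)) stop("rate constants must be >= 0")
  if (k_cb <= 0) stop("k_cb must be > 0")
  structure(p, class = "xb_params")
}

xb_param_vec <- function(params) {
  unlist(params[c("k_on", "k_off", "k_coop", "k_1", "k_force", "k_2",
                  "k_3", "k_4_0", "k_4_1", "k_cb", "kBT", "x_ps", "N_0")])
}

#' Resting cross-bridge state
#'
#' All thin-filament sites off; myosin heads partitioned between SRX and DRX
#' at the zero-force detached balance M_DRX/M_SRX = k_1/k_2; no attached
#' heads.
#'
#' @param params \code{xb_params}.
#' @param n number of integration points (rows).
#' @return numeric matrix \code{n x 25} (columns: N_off, N_on, M_SRX,
#'   M_DRX, M_FG over 21 bins).
#' @export
xb_state_init <- function(params, n = 1) {
  msrx <- params$k_2 / (params$k_1 + params$k_2)
  row <- c(1, 0, msrx, 1 - msrx, rep(0, XB_NBIN))
  matrix(row, nrow = n, ncol = 25, byrow = TRUE)
}

state_parts <- function(state) {
  s <- as.numeric(state)
  list(N_off = s[1], N_on = s[2], M_SRX = s[3], M_DRX = s[4],
       M_FG = s[5:25], N_bound = sum(s[5:25]))
}

#' Thin-filament on/off fluxes
#'
#' J_on activates binding sites at a rate proportional to calcium and the
#' unactivated overlap fraction, amplified by cooperative feedback from
#' already-active sites; J_off deactivates unbound active sites with the
#' mirrored cooperative term.
#'
#' @param state a 25-element cross-bridge state (or 1-row matrix).
#' @param ca calcium concentration (M).
#' @param n_overlap thick/thin filament overlap fraction in (0, 1].
#' @param params \code{xb_params}.
#' @return named list with \code{J_on}, \code{J_off} (1/s).
#' @export
thin_filament_fluxes <- function(state, ca, n_overlap, params) {
  p <- state_parts(state)
  if (n_overlap <= 0) {
    if (p$N_on > 0)
      stop("degenerate overlap: N_overlap = 0 with active sites present")
    return(list(J_on = 0, J_off = 0))
  }
  J_on <- params$k_on * ca * (n_overlap - p$N_on) *
    (1 + params$k_coop * p$N_on / n_overlap)
  J_off <- params$k_off * (p$N_on - p$N_bound) *
    (1 + params$k_coop * (n_overlap - p$N_on) / n_overlap)
  list(J_on = J_on, J_off = J_off)
}

#' SRX/DRX recruitment fluxes
#'
#' J_1 (SRX -> DRX) increases with the total (passive + active) stress borne
#' along the myofiber — the mechanosensitive recruitment that the disease
#' models perturb through \code{k_1}; J_2 is the first-order reverse flux.
#'
#' @param state cross-bridge state.
#' @param f_total total myofiber-direction stress (Pa); negative values are
#'   clamped to zero (no recruitment under compression).
#' @param params \code{xb_params}.
#' @return list with \code{J_1}, \code{J_2}.
#' @export
srx_drx_fluxes <- function(state, f_total, params) {
  p <- state_parts(state)
  list(J_1 = params$k_1 * (1 + params$k_force * max(f_total, 0)) * p$M_SRX,
       J_2 = params$k_2 * p$M_DRX)
}

#' Attachment/detachment fluxes per strain bin
#'
#' Attachment is distributed over the strain grid with Boltzmann weights
#' exp(-k_cb x^2 / (2 kBT)) so that the summed flux equals the attachment
#'-rate density integrated over the grid at 1 nm spacing; detachment is
#' strain dependent through k_4_0 + k_4_1 x^4.
#'
#' @param state cross-bridge state.
#' @param params \code{xb_params}.
#' @return list with vectors \code{J_3}, \code{J_4} (length 21) and the
#'   grid \code{x}.
#' @export
attach_detach_fluxes <- function(state, params) {
  p <- state_parts(state)
  if (p$N_bound > p$N_on + 1e-10)
    stop("corrupt state: N_bound exceeds N_on")
  x_m <- XB_GRID * 1e-9
  w <- exp(-params$k_cb * x_m^2 / (2 * params$kBT))
  J_3 <- params$k_3 * w * (p$N_on - p$N_bound) * p$M_DRX
  J_4 <- (params$k_4_0 + params$k_4_1 * XB_GRID^4) * p$M_FG
  list(J_3 = J_3, J_4 = J_4, x = XB_GRID)
}

#' Advance cross-bridge states over one global time step
#'
#' Applies the strain advection implied by the half-sarcomere length change
#' (attached populations shift by -dhsl on the strain grid, with boundary
#' mass forcibly detached into M_DRX), then integrates the 25-ODE system
#' with midpoint sub-steps of length \code{params$dt_sub}.  Vectorized over
#' integration points.
#'
#' @param states n x 25 state matrix.
#' @param ca calcium (M), scalar or length-n.
#' @param f_total total myofiber stress (Pa), scalar or length-n.
#' @param dhsl_nm half-sarcomere length change this step (nm), scalar or
#'   length-n.
#' @param params \code{xb_params}.
#' @param dt global step (s).
#' @param n_overlap overlap fraction, scalar or length-n (default 1).
#' @return updated state matrix.
#' @export
step_states <- function(states, ca, f_total, dhsl_nm, params, dt,
                        n_overlap = 1, k1 = params$k_1) {
  states <- rbind(states)
  n <- nrow(states)
  rep_n <- function(v) if (length(v) == 1) rep(v, n) else v
  xb_step_cpp(states, rep_n(ca), rep_n(n_overlap), rep_n(f_total),
              rep_n(dhsl_nm), xb_param_vec(params), dt, params$dt_sub,
              k1)
}

#' Active fiber stress from the attached population
#'
#' F_active = N_0 k_cb sum_i M_FG,i (x_i + x_ps), in Pa.
#'
#' @param states n x 25 state matrix (or 25-vector).
#' @param params \code{xb_params}.
#' @return numeric vector of active stresses (Pa).
#' @export
active_force <- function(states, params) {
  states <- rbind(states)
  mfg <- states[, 5:25, drop = FALSE]
  drop(params$N_0 * params$k_cb *
         (mfg %*% ((XB_GRID + params$x_ps) * 1e-9)))
}
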