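## Two-compartment intracellular calcium model.
##
## A stimulus gate opens once per pacing period and releases calcium from
## the sarcoplasmic-reticulum pool into the myoplasm; first-order re-uptake
## and a constant leak complete the cycle.  Both pools are expressed per
## myoplasmic volume, so Ca_myo + Ca_SR is conserved exactly.  Because the
## gated system is piecewise linear with constant coefficients, the periodic
## steady-state transient has a closed form, which is what
## calcium_transient() evaluates.

#' Calcium model parameters
#'
#' @param ca_total total calcium across both compartments (M, per
#'   myoplasmic volume).
#' @param k_release gated SR release rate (1/s) while the stimulus is open.
#' @param k_uptake myoplasm -> SR re-uptake rate (1/s); sets the transient
#'   decay time constant approximately 1/(k_leak + k_uptake).
#' @param k_leak constant SR leak (1/s); with k_uptake it sets the
#'   diastolic baseline k_leak * ca_total / (k_leak + k_uptake).
#' @param stim_duration stimulus-gate open time per beat (s).
#' @param period pacing period (s); default 0.937 s (64 bpm).
#' @param stim_offset time of the first stimulus within the cycle (s);
#'   lets a coupled run fill the ventricle before the first beat.
#' @return object of class \code{ca_params}.
#' @export
calcium_params <- function(ca_total = 2e-6, k_release = 200,
                           k_uptake = 7.5, k_leak = 0.395,
                           stim_duration = 0.02, period = 0.937,
                           stim_offset = 0) {
  if (any(c(k_release, k_uptake, k_leak) < 0)) stop("rates must be >= 0")
  if (ca_total <= 0) stop("ca_total must be > 0")
  if (stim_duration < 0 || stim_duration >= period)
    stop("stim_duration must lie in [0, period)")
  structure(list(ca_total = ca_total, k_release = k_release,
                 k_uptake = k_uptake, k_leak = k_leak,
                 stim_duration = stim_duration, period = period,
                 stim_offset = stim_offset),
            class = "ca_params")
}

## phase constants: dCa/dt = a - r * Ca with
##   release phase: a1 = (k_leak + k_release) * T, r1 = k_leak + k_release + k_up
##   decay phase:   a2 = k_leak * T,              r2 = k_leak + k_up
ca_phase_constants <- function(p) {
  r1 <- p$k_leak + p$k_release + p$k_uptake
  r2 <- p$k_leak + p$k_uptake
  list(A1 = (p$k_leak + p$k_release) * p$ca_total / r1, r1 = r1,
       A2 = p$k_leak * p$ca_total / r2, r2 = r2)
}

## myoplasmic calcium at the start of a cycle in periodic steady state
ca_cycle_start <- function(p) {
  k <- ca_phase_constants(p)
  t1 <- p$stim_duration
  t2 <- p$period - t1
  e1 <- exp(-k$r1 * t1)
  e2 <- exp(-k$r2 * t2)
  ## c0 = A2 + ((A1 + (c0 - A1) e1) - A2) e2
  (k$A2 * (1 - e2) + (k$A1 * (1 - e1)) * e2) / (1 - e1 * e2)
}

#' Periodic myoplasmic calcium transient
#'
#' Evaluates the periodic steady-state myoplasmic calcium concentration of
#' the two-compartment model at arbitrary times (closed form; no numerical
#' integration).
#'
#' @param t time(s) in seconds; interpreted modulo the pacing period.
#' @param params \code{ca_params}.
#' @return calcium concentration(s) in M.
#' @export
calcium_transient <- function(t, params) {
  p <- params
  k <- ca_phase_constants(p)
  c0 <- ca_cycle_start(p)
  off <- if (is.null(p$stim_offset)) 0 else p$stim_offset
  tau <- (t - off) %% p$period
  if (off > 0) tau[t < off] <- p$period - 1e-9 # pre-stimulus rest
  t1 <- p$stim_duration
  c1 <- k$A1 + (c0 - k$A1) * exp(-k$r1 * pmin(tau, t1))
  cend <- k$A1 + (c0 - k$A1) * exp(-k$r1 * t1)
  out <- ifelse(tau <= t1, c1, k$A2 + (cend - k$A2) * exp(-k$r2 * (tau - t1)))
  as.numeric(out)
}

#' Diastolic calcium baseline of the model
#'
#' The fixed point of the decay phase, k_leak * ca_total /
#' (k_leak + k_uptake) — the concentration the transient decays toward
#' between beats.
#'
#' @param params \code{ca_params}.
#' @return concentration in M.
#' @export
calcium_baseline <- function(params) {
  ca_phase_constants(params)$A2
}
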