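## Standalone sarcomere protocols: isometric twitch, length ramp,
## force-pCa sweep.  These exercise the contraction model without the
## finite-element ventricle and are the basis of its unit and oracle
## tests.

#' Isometric twitch protocol
#'
#' Paces a single half-sarcomere at fixed length with the periodic calcium
#' transient and records activation and force.
#'
#' @param params \code{xb_params}.
#' @param calcium \code{ca_params}.
#' @param duration_s protocol length (s).
#' @param dt_s global step (s).
#' @param k1 optional k_1 override (1/s).
#' @return data.frame: time_s, ca_M, N_on, M_SRX, M_DRX, N_bound,
#'   F_active_Pa.
#' @export
twitch_protocol <- function(params = xb_params(),
                            calcium = calcium_params(),
                            duration_s = 0.937, dt_s = 1e-3,
                            k1 = params$k_1) {
  n <- round(duration_s / dt_s)
  st <- xb_state_init(params)
  out <- data.frame(time_s = (1:n) * dt_s, ca_M = NA_real_,
                    N_on = NA_real_, M_SRX = NA_real_, M_DRX = NA_real_,
                    N_bound = NA_real_, F_active_Pa = NA_real_)
  f <- 0
  for (i in 1:n) {
    ca <- calcium_transient(i * dt_s, calcium)
    st <- step_states(st, ca, f, 0, params, dt_s, k1 = k1)
    f <- active_force(st, params)
    out[i, -1] <- c(ca, st[1, 2], st[1, 3], st[1, 4], sum(st[1, 5:25]), f)
  }
  out
}

#' Length-ramp protocol
#'
#' Applies a linear half-sarcomere length ramp during tetanic (constant)
#' calcium activation and records the force response of the attached
#' cross-bridge distribution.
#'
#' @param params \code{xb_params}.
#' @param ca constant calcium (M).
#' @param ramp_nm total length change (nm), applied linearly.
#' @param ramp_start_s,ramp_dur_s ramp timing.
#' @param duration_s protocol length (s).
#' @param dt_s global step (s).
#' @return data.frame: time_s, dhsl_nm, F_active_Pa.
#' @export
length_ramp_protocol <- function(params = xb_params(), ca = 1e-6,
                                 ramp_nm = -10, ramp_start_s = 0.3,
                                 ramp_dur_s = 0.05, duration_s = 0.5,
                                 dt_s = 1e-3) {
  n <- round(duration_s / dt_s)
  st <- xb_state_init(params)
  out <- data.frame(time_s = (1:n) * dt_s, dhsl_nm = 0,
                    F_active_Pa = NA_real_)
  f <- 0
  for (i in 1:n) {
    t0 <- (i - 1) * dt_s
    dh <- 0
    if (t0 >= ramp_start_s && t0 < ramp_start_s + ramp_dur_s)
      dh <- ramp_nm * dt_s / ramp_dur_s
    st <- step_states(st, ca, f, dh, params, dt_s)
    f <- active_force(st, params)
    out$dhsl_nm[i] <- dh
    out$F_active_Pa[i] <- f
  }
  out
}

#' Steady-state force-pCa relation
#'
#' Holds calcium constant at each level until the force plateaus and
#' reports the steady active stress.
#'
#' @param params \code{xb_params}.
#' @param pca pCa values (-log10 of molar calcium).
#' @param settle_s settling time per level (s).
#' @param dt_s step (s).
#' @return data.frame: pCa, ca_M, F_active_Pa.
#' @export
force_pca_curve <- function(params = xb_params(), pca = seq(7, 4.5, -0.25),
                            settle_s = 3, dt_s = 1e-3) {
  out <- data.frame(pCa = pca, ca_M = 10^(-pca), F_active_Pa = NA_real_)
  for (j in seq_along(pca)) {
    st <- xb_state_init(params)
    f <- 0
    for (i in seq_len(round(settle_s / dt_s))) {
      st <- step_states(st, out$ca_M[j], f, 0, params, dt_s)
      f <- active_force(st, params)
    }
    out$F_active_Pa[j] <- f
  }
  out
}
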