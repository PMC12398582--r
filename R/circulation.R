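## Seven-compartment closed-loop Windkessel circulation.
##
## Compartment order follows the flow path:
##   ventricle -> aorta -> arteries -> arterioles -> capillaries ->
##   venules -> veins -> ventricle
## Each inter-compartment resistance is named after the compartment the
## flow enters (aortic valve = "aorta", mitral inflow = "ventricle").

#' Compartment names of the systemic loop
#' @export
circ_compartments <- c("aorta", "arteries", "arterioles", "capillaries",
                       "venules", "veins", "ventricle")

#' Construct circulation parameters
#'
#' Lumped-parameter description of the systemic circulation: one resistance
#' per inter-compartment connection and one compliance + slack volume per
#' non-ventricular compartment.  All values in SI units (Pa s / m^3,
#' m^3 / Pa, m^3).
#'
#' @param resistances named numeric, one per compartment in
#'   \code{circ_compartments}; \code{resistances["aorta"]} is the aortic
#'   valve resistance and \code{resistances["ventricle"]} the mitral inflow
#'   resistance.
#' @param compliances named numeric over the six non-ventricular
#'   compartments.
#' @param slack_volumes named numeric over the six non-ventricular
#'   compartments; the compartment pressure is zero at its slack volume.
#' @param total_volume total blood volume (m^3) of the closed loop.
#' @return an object of class \code{circ_params}.
#' @export
circulation_params <- function(resistances, compliances, slack_volumes,
                               total_volume) {
  nonlv <- setdiff(circ_compartments, "ventricle")
  resistances <- resistances[circ_compartments]
  compliances <- compliances[nonlv]
  slack_volumes <- slack_volumes[nonlv]
  if (anyNA(resistances)) stop("resistances must be named for all compartments")
  if (anyNA(compliances)) stop("compliances must be named for all non-LV compartments")
  if (anyNA(slack_volumes)) stop("slack volumes must be named for all non-LV compartments")
  if (any(resistances <= 0)) stop("all resistances must be > 0")
  if (any(compliances <= 0)) stop("all compliances must be > 0")
  if (any(slack_volumes < 0)) stop("slack volumes must be >= 0")
  if (!is.numeric(total_volume) || total_volume <= 0)
    stop("total_volume must be a positive number")
  structure(list(resistances = resistances, compliances = compliances,
                 slack_volumes = slack_volumes, total_volume = total_volume),
            class = "circ_params")
}

#' Initialize circulation state from an operating point
#'
#' Distributes blood so each non-ventricular compartment sits at a target
#' pressure; all remaining blood is assigned to the veins (the high-capacity
#' reservoir), which perturbs the venous pressure away from its target but
#' keeps the loop volume exactly at \code{params$total_volume}.
#'
#' @param params \code{circ_params}.
#' @param pressures named numeric (Pa) of target initial pressures for the
#'   six non-ventricular compartments.
#' @param v_lv initial ventricular cavity volume (m^3).
#' @return named numeric vector of compartment volumes (class
#'   \code{circ_state}).
#' @export
circulation_init <- function(params, pressures, v_lv) {
  nonlv <- setdiff(circ_compartments, "ventricle")
  pressures <- pressures[nonlv]
  if (anyNA(pressures)) stop("initial pressures must cover all non-LV compartments")
  v <- params$slack_volumes + pressures * params$compliances
  rest <- params$total_volume - sum(v[setdiff(nonlv, "veins")]) - v_lv
  if (rest <= params$slack_volumes[["veins"]])
    stop("total blood volume too small for the requested operating point")
  v[["veins"]] <- rest
  state <- c(v, ventricle = v_lv)[circ_compartments]
  class(state) <- "circ_state"
  state
}

#' Pressures of the non-ventricular compartments
#'
#' P_i = (V_i - V_slack,i) / C_i.  The ventricular pressure is NOT computed
#' here; in a coupled run it is supplied by the finite-element solve as the
#' cavity-pressure Lagrange multiplier.
#'
#' @param state named compartment volumes (m^3).
#' @param params \code{circ_params}.
#' @return named numeric vector of six pressures (Pa).
#' @export
compartment_pressures <- function(state, params) {
  nonlv <- setdiff(circ_compartments, "ventricle")
  (unclass(state)[nonlv] - params$slack_volumes[nonlv]) /
    params$compliances[nonlv]
}

#' Inter-compartment flows of the loop
#'
#' Ohm's law along the loop: each flow equals the pressure drop between
#' adjacent compartments over the connecting resistance.  The two valves are
#' one-way: flow into the aorta is zero unless the ventricular pressure
#' reaches aortic pressure, and ventricular inflow is zero unless venous
#' pressure reaches ventricular pressure.
#'
#' @param pressures named numeric of all seven compartment pressures (Pa),
#'   including \code{ventricle}.
#' @param params \code{circ_params}.
#' @return named numeric of seven flows (m^3/s); \code{flows[i]} is the flow
#'   entering compartment \code{i} from its upstream neighbour.
#' @export
circulation_flows <- function(pressures, params) {
  p <- pressures[circ_compartments]
  if (anyNA(p)) stop("pressures must be named for all compartments (incl. ventricle)")
  upstream <- c(circ_compartments[length(circ_compartments)],
                circ_compartments[-length(circ_compartments)])
  q <- (p[upstream] - p) / params$resistances
  names(q) <- circ_compartments
  # aortic valve: ventricle -> aorta only when P_LV >= P_aorta
  if (p[["ventricle"]] < p[["aorta"]]) q[["aorta"]] <- 0
  # mitral inflow: veins -> ventricle only when P_veins >= P_LV
  if (p[["veins"]] < p[["ventricle"]]) q[["ventricle"]] <- 0
  q
}

#' Explicit volume update of the loop
#'
#' Forward-Euler update of dV_i/dt = Q_in,i - Q_out,i.  Because every flow
#' appears exactly once as an inflow and once as an outflow, the total blood
#' volume is conserved to round-off.
#'
#' @param state named compartment volumes (m^3).
#' @param flows named flows from \code{\link{circulation_flows}}.
#' @param dt time step (s).
#' @return updated \code{circ_state}.
#' @export
step_volumes <- function(state, flows, dt) {
  if (dt <= 0) stop("dt must be > 0")
  q_in <- flows[circ_compartments]
  nxt <- c(circ_compartments[-1], circ_compartments[1])
  q_out <- flows[nxt]
  new <- unclass(state)[circ_compartments] + dt * (q_in - q_out)
  names(new) <- circ_compartments
  if (any(new < 0))
    stop("negative compartment volume after update: time step too large ",
         "or unphysical parameters")
  class(new) <- "circ_state"
  new
}
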