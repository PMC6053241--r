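#' Cortical dendritic right-hand side
#'
#' Evaluates the dendritic current balance of the two-compartment cortical
#' cell at one instant:
#' `C_m dV_D/dt = -ACh_gkl*I_KL - I_Na - I_Na(p) - I_Km - I_KCa - I_HVA -
#' I_L - g(V_D - V_S) - I_syn`, together with the gating derivatives
#' `dx/dt = -(x - x_inf)/tau_x` (time constants carry the 1/Q_T
#' temperature factor). The axosomatic voltage is taken at its equilibrium
#' value unless supplied.
#'
#' @param state named numeric state: `V_D`, dendritic gates `m_Na`, `h_Na`,
#'   `m_Nap`, `n_Km`, `m_KCa`, `m_HVA`, `h_HVA`, `Ca`, axosomatic gates
#'   `m_Na_s`, `h_Na_s`, `n_K_s`, `m_Nap_s`. Use [cortical_state()] for a
#'   resting-state template.
#' @param params a PY or IN [cell_params()].
#' @param ach_gkl stage potassium-leak factor (> 0).
#' @param I_syn synaptic current density on the dendrite (uA/cm2).
#' @param I_stim injected current density (uA/cm2, depolarizing positive).
#' @param V_S axosomatic voltage; `NA` (default) solves the equilibrium.
#' @return list with `dstate` (named derivatives) and `V_S`.
#' @export
cortical_dendrite_rhs <- function(state, params, ach_gkl, I_syn = 0,
                                  I_stim = 0, V_S = NA_real_) {
  stopifnot(ach_gkl > 0)
  s <- as_cx_state(state)
  out <- .cx_dendrite_rhs(s, unclass(params), ach_gkl, I_syn, I_stim, V_S)
  names(out$dstate) <- names(s)
  out
}

cx_state_names <- c("V_D", "m_Na", "h_Na", "m_Nap", "n_Km", "m_KCa",
                    "m_HVA", "h_HVA", "Ca", "m_Na_s", "h_Na_s", "n_K_s",
                    "m_Nap_s")
tc_state_names <- c("V", "m_Na", "h_Na", "n_K", "m_T", "h_T", "O_h", "P1_h",
                    "OL_h", "Ca")
re_state_names <- c("V", "m_Na", "h_Na", "n_K", "m_T", "h_T", "Ca")

as_cx_state <- function(state) {
  if (is.null(names(state))) {
    stopifnot(length(state) == length(cx_state_names))
    return(stats::setNames(as.numeric(state), cx_state_names))
  }
  stopifnot(all(cx_state_names %in% names(state)))
  stats::setNames(as.numeric(state[cx_state_names]), cx_state_names)
}

#' Resting cortical / thalamic state templates
#'
#' Builds a state vector at voltage `V` with every gating variable at its
#' steady state and the calcium pool at its resting value.
#'
#' @param V membrane voltage (mV).
#' @param params a [cell_params()].
#' @return named numeric state vector suitable for the `*_rhs` operations.
#' @export
cortical_state <- function(V, params = cell_params("PY")) {
  s <- stats::setNames(numeric(13), cx_state_names)
  s["V_D"] <- V
  # each gate's derivative is linear in x: two evaluations recover x_inf;
  # two passes resolve the calcium dependence of the KCa gate
  for (pass in 1:2)
    for (k in 2:13) s[k] <- gate_inf_from_rhs(s, params, k, V)
  s
}

gate_inf_from_rhs <- function(s, params, k, V) {
  # dx/dt = (inf - x)/tau; evaluate at x = 0 and x = 1 to recover inf
  s0 <- s; s0[k] <- 0
  s1 <- s; s1[k] <- 1
  d0 <- .cx_dendrite_rhs(s0, unclass(params), 1, 0, 0, V)$dstate[k]
  d1 <- .cx_dendrite_rhs(s1, unclass(params), 1, 0, 0, V)$dstate[k]
  if (isTRUE(all.equal(d0, d1))) return(s[k])
  d0 / (d0 - d1)
}

#' Axosomatic equilibrium voltage
#'
#' Solves the axosomatic current balance `0 = -g(V_S - V_D) - I_Na - I_K -
#' I_Na(p)` for `V_S` at fixed gating state. Because every axosomatic
#' current is ohmic in `V_S` once the gating variables are held as state,
#' the balance has a closed-form root; a safeguarded Newton refinement
#' guarantees the configured residual tolerance regardless.
#'
#' @param V_D dendritic voltage (mV).
#' @param soma_gating numeric length-4: `m_Na`, `h_Na`, `n_K`, `m_Nap`.
#' @param params a PY or IN [cell_params()].
#' @param tol relative residual tolerance (default 1e-6).
#' @param max_iter iteration cap for the refinement.
#' @return list with `V_S`, `residual` (uA/cm2) and `iterations`.
#' @export
solve_axosomatic_equilibrium <- function(V_D, soma_gating, params,
                                         tol = 1e-6, max_iter = 100) {
  stopifnot(length(soma_gating) == 4)
  .solve_vs(V_D, as.numeric(soma_gating), unclass(params), tol, max_iter)
}

#' Thalamic single-compartment right-hand side
#'
#' `C_m dV/dt = -ACh_gkl*I_KL - I_Na - I_K - I_T - I_h - I_L - I_syn`, with
#' the hyperpolarization-activated current present only in TC cells (its
#' activation curve shifted by `ha_gh`).
#'
#' @param state named numeric state: `V`, `m_Na`, `h_Na`, `n_K`, `m_T`,
#'   `h_T`, (`m_h` for TC), `Ca`.
#' @param params a TC or RE [cell_params()].
#' @param ach_gkl stage potassium-leak factor.
#' @param ha_gh stage shift of the h-current activation curve (mV).
#' @param I_syn synaptic current density (uA/cm2).
#' @param I_stim injected current density (uA/cm2).
#' @return list with `dstate` (named derivatives).
#' @export
thalamic_rhs <- function(state, params, ach_gkl, ha_gh = 0, I_syn = 0,
                         I_stim = 0) {
  is_tc <- params$cell_kind == "TC"
  nm <- if (is_tc) tc_state_names else re_state_names
  if (!is.null(names(state))) state <- state[nm]
  stopifnot(length(state) == length(nm))
  out <- .thalamic_rhs(as.numeric(state), unclass(params), is_tc, ach_gkl,
                       ha_gh, I_syn, I_stim)
  names(out$dstate) <- nm
  out
}

#' Integrate a single isolated cell
#'
#' RK4 integration of one cell with a step-current protocol, used for
#' regime-level single-cell behaviour (tonic firing of a pyramidal cell
#' under depolarizing drive, low-threshold rebound bursts of a relay cell
#' released from hyperpolarization).
#'
#' @param params a [cell_params()].
#' @param stage a [stage_params()] or stage label; supplies the leak
#'   factor and h-current shift.
#' @param duration simulated time (ms).
#' @param stim matrix with columns `t_on`, `t_off`, `amp` (uA/cm2), or
#'   NULL.
#' @param dt integration step (ms, default 0.02).
#' @param v0 initial voltage (default the leak reversal).
#' @param record_every store the voltage every this many steps
#'   (default 5 = 0.1 ms sampling).
#' @return list with `t`, `v` (axosomatic voltage for cortical cells) and
#'   `spikes` (upward zero-crossing times).
#' @export
single_cell <- function(params, stage = "awake", duration = 1000,
                        stim = NULL, dt = 0.02, v0 = NULL,
                        record_every = 5) {
  if (!inherits(stage, "stage_params")) stage <- stage_params(stage)
  kind <- params$cell_kind
  gkl <- unname(stage$ach_gkl[kind])
  if (is.null(stim)) stim <- matrix(numeric(0), 0, 3)
  if (is.null(v0)) v0 <- params$E_L
  .single_cell_run(kind, unclass(params), gkl, stage$ha_gh, duration, dt,
                   stim, v0, as.integer(record_every))
}

#' Receptor kinetics driven by a presynaptic spike train
#'
#' Integrates the first-order transmitter-gated kinetics (AMPA, NMDA,
#' GABA-A) or the G-protein cascade (GABA-B) of one synapse for a given
#' train of presynaptic spikes, returning the open fraction (or the
#' potassium-channel activation for GABA-B) over time.
#'
#' @param receptor `"AMPA"`, `"NMDA"`, `"GABAA"` or `"GABAB"`.
#' @param spike_times presynaptic spike times (ms).
#' @param duration simulated time (ms).
#' @param dt integration step (ms).
#' @return data.frame with `t`, `value` (and `R`, `G` for GABA-B).
#' @export
synapse_response <- function(receptor = c("AMPA", "NMDA", "GABAA", "GABAB"),
                             spike_times, duration = 1000, dt = 0.02) {
  receptor <- match.arg(receptor)
  code <- match(receptor, c("AMPA", "NMDA", "GABAA", "GABAB")) - 1L
  out <- .synapse_response(code, as.numeric(spike_times), duration, dt)
  if (receptor == "GABAB")
    data.frame(t = out$t, value = out$value, R = out$R, G = out$G)
  else data.frame(t = out$t, value = out$value)
}
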