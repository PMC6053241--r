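#' Temperature scaling factor for gating kinetics
#'
#' All gating time constants are divided by `Q^((T - 23)/10)`; with the
#' defaults (Q = 2.3, T = 36 C) this evaluates to 2.9529.
#'
#' @param Q kinetic Q10-style base (default 2.3).
#' @param temp simulation temperature in C (default 36).
#' @param ref reference temperature in C (default 23).
#' @return dimensionless scaling factor.
#' @export
qt_factor <- function(Q = 2.3, temp = 36, ref = 23) Q^((temp - ref) / 10)

#' Intrinsic cell parameters
#'
#' Default single-cell parameters per cell kind: cortical pyramidal (PY)
#' and inhibitory (IN) neurons are two-compartment (dendrite + axosomatic)
#' models, thalamic relay (TC) and reticular (RE) neurons are single
#' compartment. Conductances in mS/cm2, areas in cm2, potentials in mV,
#' capacitance in uF/cm2. The hyperpolarization-activated current is
#' restricted to TC cells and the persistent sodium current to PY cells.
#'
#' @param kind one of `"PY"`, `"IN"`, `"TC"`, `"RE"`.
#' @param ... named overrides of individual fields.
#' @return a named list of class `cell_params`.
#' @export
cell_params <- function(kind = c("PY", "IN", "TC", "RE"), ...) {
  kind <- match.arg(kind)
  p <- switch(kind,
    PY = list(
      cell_kind = "PY", C_m = 0.75,
      S_soma = 1.0e-6, rho = 165,
      # axosomatic compartment
      g_Na_soma = 3000, g_K_soma = 200, g_Nap_soma = 15,
      # dendritic compartment
      g_Na_dend = 0.8, g_Nap_dend = 2.5, g_Km = 0.02, g_KCa = 0.05,
      g_HVA = 0.01,
      G_L = 0.009, E_L = -67, G_KL = 0.011, E_K = -95,
      kappa_Mohm = 10,
      na_m_mid = -35, na_h_mid = -65, kv_mid = 5, nap_max = 0.012),
    IN = list(
      cell_kind = "IN", C_m = 0.75,
      S_soma = 1.0e-6, rho = 50,
      g_Na_soma = 2500, g_K_soma = 200, g_Nap_soma = 0,
      g_Na_dend = 0.8, g_Nap_dend = 0, g_Km = 0.015, g_KCa = 0.05,
      g_HVA = 0.01,
      G_L = 0.009, E_L = -70, G_KL = 0.009, E_K = -95,
      kappa_Mohm = 10,
      na_m_mid = -35, na_h_mid = -65, kv_mid = 5, nap_max = 0.012),
    TC = list(
      cell_kind = "TC", C_m = 1,
      S = 2.9e-4,
      g_Na = 90, g_K = 12, g_T = 2.5, g_h = 0.016,
      G_L = 0.01, E_L = -70, G_KL = 0.024, E_K = -95,
      V_tr = -55, V_trK = -70, E_h = -40),
    RE = list(
      cell_kind = "RE", C_m = 1,
      S = 1.43e-4,
      g_Na = 100, g_K = 10, g_T = 2.2, g_h = 0,
      G_L = 0.05, E_L = -77, G_KL = 0.012, E_K = -95,
      V_tr = -55, V_trK = -70, E_h = -40))
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown cell parameter(s): ",
                          paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  if (p$cell_kind == "RE" && isTRUE(p$g_h > 0))
    stop("the hyperpolarization-activated current is TC-only: g_h must be 0 for RE")
  if (p$cell_kind == "IN" && (isTRUE(p$g_Nap_soma > 0) || isTRUE(p$g_Nap_dend > 0)))
    stop("the persistent sodium current is PY-only: g_Nap must be 0 for IN")
  num <- vapply(p[-1], is.numeric, logical(1))
  if (any(unlist(p[-1][num]) < 0 &
          grepl("^(g_|G_)", names(p[-1])[num])))
    stop("conductances must be >= 0")
  p$Q_T <- qt_factor()
  class(p) <- "cell_params"
  p
}

#' Steady-state activation of the hyperpolarization-activated current
#'
#' `m_inf = 1 / (1 + exp((V + 75 + HA_gh) / 5.5))`: a sigmoid decreasing in
#' V, with the histamine level of the active stage entering as a shift
#' `HA_gh` of the half-activation voltage (-24 mV awake, -2 mV N2,
#' -1 mV N3).
#'
#' @param V membrane voltage (mV).
#' @param ha_gh stage-dependent activation shift (mV).
#' @return activation in \[0, 1\].
#' @examples
#' ih_activation(-51, ha_gh = -24)  # 0.5 at the shifted midpoint
#' @export
ih_activation <- function(V, ha_gh = 0) 1 / (1 + exp((V + 75 + ha_gh) / 5.5))

#' Miniature-PSP Poisson intensity
#'
#' Rate (events per ms) of the spontaneous miniature PSP process on a
#' synapse whose presynaptic neuron last spiked at `t0`:
#' `mu(t) = (2 / (1 + exp(-(t - t0)/F)) - 1) / 250`. The rate is 0 at the
#' moment of the spike and saturates at 1/250 per ms.
#'
#' @param t current time (ms).
#' @param t0 last presynaptic spike time (ms).
#' @param F time scale in ms (30 for all cortical mini projections).
#' @return rate per ms (clamped to 0 for `t < t0`).
#' @export
mini_rate <- function(t, t0, F = 30) {
  pmax(0, (2 / (1 + exp(-(t - t0) / F)) - 1) / 250)
}
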