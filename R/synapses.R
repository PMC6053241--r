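#' Synaptic current for one receptor type
#'
#' Evaluates `I = factor * g_syn * [O] * (V_post - E_rev)` for AMPA,
#' NMDA and GABA-A receptors, and
#' `I = factor * g_syn * act * (V_post - E_K)` for GABA-B, where `act` is
#' the potassium-channel activation produced by the G-protein cascade
#' (`G^4 / (G^4 + K_d)`, see [synapse_response()]). The neuromodulator
#' factor is looked up from the stage for the modulated projections
#' (AMPA: PY-PY, TC-PY, TC-IN; GABA-A: IN-PY, RE-RE, RE-TC) and is 1
#' otherwise; NMDA additionally carries its voltage-dependent magnesium
#' block.
#'
#' @param receptor `"AMPA"`, `"NMDA"`, `"GABAA"` or `"GABAB"`.
#' @param open open fraction `[O]` (for GABA-B: the G-protein
#'   concentration `G`).
#' @param V_post postsynaptic voltage (mV).
#' @param g_syn maximal conductance (uS).
#' @param projection projection name for stage modulation, e.g.
#'   `"PY->PY/AMPA"`; NULL for no modulation.
#' @param stage a [stage_params()] or stage label; NULL for factor 1.
#' @param gabab_kd half-activation constant of the cascade (default 100).
#' @return current in uS * mV (nA).
#' @export
synaptic_current <- function(receptor = c("AMPA", "NMDA", "GABAA", "GABAB"),
                             open, V_post, g_syn, projection = NULL,
                             stage = NULL, gabab_kd = 100) {
  receptor <- match.arg(receptor)
  e_rev <- c(AMPA = 0, NMDA = 0, GABAA = -70, GABAB = -95)[[receptor]]
  f <- if (!is.null(projection) && !is.null(stage))
    stage_synaptic_factor(projection, stage) else 1
  gate <- switch(receptor,
    NMDA = open / (1 + exp(-(V_post + 25) / 12.5)),
    GABAB = open^4 / (open^4 + gabab_kd),
    open)
  f * g_syn * gate * (V_post - e_rev)
}
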