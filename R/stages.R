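#' Neuromodulator state of a vigilance stage
#'
#' The three simulated stages (awake, N2, N3) differ only in neuromodulator
#' levels, implemented as multiplicative factors and one voltage shift:
#' acetylcholine scales the potassium leak conductance (`ach_gkl`, per cell
#' kind) and the AMPA strength of cortical PY and thalamocortical
#' projections (`ach_ampa`, per source kind); GABA level scales GABA-A
#' strength of IN and RE projections (`gaba_gabaa`); histamine shifts the
#' activation curve of the TC hyperpolarization-activated current
#' (`ha_gh`, mV).
#'
#' @param stage `"awake"`, `"n2"` or `"n3"`.
#' @return list of class `stage_params` with fields `stage`, `ach_gkl`
#'   (named: PY, IN, TC, RE), `ach_ampa` (PY, TC), `gaba_gabaa` (IN, RE),
#'   `ha_gh`, and `stdp` (see [stage_plasticity()]).
#' @export
stage_params <- function(stage = c("awake", "n2", "n3")) {
  stage <- match.arg(tolower(stage), c("awake", "n2", "n3"))
  i <- match(stage, c("awake", "n2", "n3"))
  out <- list(
    stage = stage,
    ach_gkl = c(PY = c(0.133, 0.228, 0.38)[i],
                IN = c(0.133, 0.228, 0.38)[i],
                TC = c(0.4, 0.96, 1.6)[i],
                RE = c(0.9, 0.81, 0.45)[i]),
    ach_ampa = c(PY = c(0.133, 0.1938, 0.4332)[i],
                 TC = c(0.6, 0.72, 1.2)[i]),
    gaba_gabaa = c(IN = c(0.22, 0.264, 0.44)[i],
                   RE = c(0.6, 0.72, 1.2)[i]),
    ha_gh = c(-24, -2, -1)[i],
    stdp = stage_plasticity(stage))
  class(out) <- "stage_params"
  out
}

# Projections whose AMPA (resp. GABA-A) strength is stage-scaled.
AMPA_SCALED <- c("PY->PY/AMPA", "TC->PY/AMPA", "TC->IN/AMPA")
GABA_SCALED <- c("IN->PY/GABAA", "RE->RE/GABAA", "RE->TC/GABAA")

#' Stage-scaling factor for one projection
#'
#' Returns the multiplicative neuromodulator factor applied to a
#' projection's synaptic current in a given stage: the acetylcholine AMPA
#' factor of the source population for the modulated AMPA projections
#' (PY-PY, TC-PY, TC-IN), the GABA factor for the modulated GABA-A
#' projections (IN-PY, RE-RE, RE-TC), and 1 otherwise (NMDA, GABA-B, and
#' corticothalamic AMPA are unscaled).
#'
#' @param projection projection name, e.g. `"PY->PY/AMPA"`.
#' @param stage a [stage_params()] object or stage label.
#' @return numeric scalar factor.
#' @export
stage_synaptic_factor <- function(projection, stage) {
  if (!inherits(stage, "stage_params")) stage <- stage_params(stage)
  src <- sub("->.*", "", projection)
  if (projection %in% AMPA_SCALED) unname(stage$ach_ampa[src])
  else if (projection %in% GABA_SCALED) unname(stage$gaba_gabaa[src])
  else 1
}

#' Stage-dependent plasticity parameters
#'
#' Symmetric STDP amplitudes per stage: `A+ = A- = 0.002` in awake and N2,
#' reduced to `0.001` during N3 (slow-wave) sleep to reflect the low
#' acetylcholine level. Time constants are 20 ms, the mini-amplitude
#' co-plasticity factor is `f = 0.01`, and weights are bounded to
#' \[0, 200%\] of their initial value.
#'
#' @param stage `"awake"`, `"n2"` or `"n3"`.
#' @return list with `A_plus`, `A_minus`, `tau_plus`, `tau_minus`, `f`,
#'   `bound_frac` (the 200% cap as a fraction, 2).
#' @export
stage_plasticity <- function(stage = c("awake", "n2", "n3")) {
  stage <- match.arg(tolower(stage), c("awake", "n2", "n3"))
  A <- if (stage == "n3") 0.001 else 0.002
  list(A_plus = A, A_minus = A, tau_plus = 20, tau_minus = 20,
       f = 0.01, bound_frac = 2)
}
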