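#' Symmetric STDP modification function
#'
#' `F(dt) = A+ * exp(-|dt|/tau+)` for `dt > 0` (pre before post,
#' potentiation) and `-A- * exp(-|dt|/tau-)` for `dt < 0` (depression).
#' `dt = 0` exactly returns 0 (no update): the function is undefined there
#' and simultaneous spikes at the integration resolution are a
#' measure-zero tie, broken by doing nothing.
#'
#' @param dt spike-timing difference `t_post - t_pre` in ms (vectorized).
#' @param params plasticity parameters, e.g. [stage_plasticity()].
#' @return dimensionless modification, same length as `dt`.
#' @examples
#' stdp_F(20)          # 0.002 * exp(-1)
#' stdp_F(-10) == -stdp_F(10)
#' @export
stdp_F <- function(dt, params = stage_plasticity("awake")) {
  ifelse(dt > 0, params$A_plus * exp(-abs(dt) / params$tau_plus),
         ifelse(dt < 0, -params$A_minus * exp(-abs(dt) / params$tau_minus), 0))
}

#' Apply one STDP pairing to a synapse
#'
#' Updates the AMPA weight by `g_max * F(dt)` and the mini amplitude by
#' `f * A_mini_ref * F(dt)`, then clips both to \[0, 200%\] of their
#' initial values.
#'
#' @param weight current AMPA weight (uS).
#' @param weight_init initial AMPA weight defining the clip bounds.
#' @param dt spike-timing difference `t_post - t_pre` (ms).
#' @param g_max maximal AMPA conductance entering the update (uS); by
#'   convention the projection's unnormalized conductance (0.24 uS for
#'   PY-PY).
#' @param mini_amp,mini_amp_init current and initial mini amplitude (mV);
#'   optional.
#' @param A_mini_ref reference mini amplitude in the mini update
#'   (default 0.2 mV).
#' @param params plasticity parameters (see [stage_plasticity()]).
#' @return list with updated `weight` and `mini_amp`.
#' @export
apply_stdp <- function(weight, weight_init, dt, g_max = 0.24,
                       mini_amp = NULL, mini_amp_init = NULL,
                       A_mini_ref = 0.2,
                       params = stage_plasticity("awake")) {
  f_dt <- stdp_F(dt, params)
  w <- clip(weight + g_max * f_dt, 0, params$bound_frac * weight_init)
  ma <- if (!is.null(mini_amp))
    clip(mini_amp + params$f * A_mini_ref * f_dt, 0,
         params$bound_frac * mini_amp_init)
  list(weight = w, mini_amp = ma)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Train a weight matrix from a spike raster (offline STDP)
#'
#' Applies the STDP rule with nearest-neighbor pairing to the PY-PY
#' synapses of a connectivity map, given a raster of pre/post spike times.
#' Each postsynaptic spike pairs with the most recent preceding presynaptic
#' spike (potentiation), and each presynaptic spike pairs with the most
#' recent preceding postsynaptic spike (depression). This is the same rule
#' the engine applies online; the offline version supports training-on-
#' raster experiments and property tests of the rule itself.
#'
#' @param connectivity a [build_connectivity()] map.
#' @param raster a [spike_raster()] of the PY population.
#' @param params plasticity parameters.
#' @param g_max maximal conductance entering each update (default the
#'   projection's unnormalized PY-PY conductance).
#' @return the connectivity map with updated PY-PY AMPA `weight` and
#'   `mini_amp` columns.
#' @export
train_stdp <- function(connectivity, raster,
                       params = stage_plasticity("awake"), g_max = NULL) {
  syn <- connectivity$projections[["PY->PY/AMPA"]]
  if (is.null(g_max)) g_max <- connectivity$weights[["PY->PY/AMPA"]]
  w <- syn$weight; w0 <- syn$weight_init
  ma <- syn$mini_amp; ma0 <- syn$mini_amp_init
  spk <- split(raster$time, raster$neuron)
  last <- rep(-Inf, attr(raster, "n_neurons"))
  by_pre <- split(seq_len(nrow(syn)), syn$pre)
  by_post <- split(seq_len(nrow(syn)), syn$post)
  ev_n <- raster$neuron; ev_t <- raster$time
  for (k in seq_along(ev_t)) {
    nrn <- ev_n[k]; t <- ev_t[k]
    post_syn <- by_post[[as.character(nrn)]]
    for (s in post_syn) {                    # this spike as POST: dt > 0
      dt <- t - last[syn$pre[s]]
      if (is.finite(dt) && dt > 0) {
        u <- apply_stdp(w[s], w0[s], dt, g_max, ma[s], ma0[s],
                        params = params)
        w[s] <- u$weight; ma[s] <- u$mini_amp
      }
    }
    pre_syn <- by_pre[[as.character(nrn)]]
    for (s in pre_syn) {                     # this spike as PRE: dt < 0
      dt <- last[syn$post[s]] - t
      if (is.finite(dt) && dt < 0) {
        u <- apply_stdp(w[s], w0[s], dt, g_max, ma[s], ma0[s],
                        params = params)
        w[s] <- u$weight; ma[s] <- u$mini_amp
      }
    }
    last[nrn] <- t
  }
  syn$weight <- w; syn$mini_amp <- ma
  connectivity$projections[["PY->PY/AMPA"]] <- syn
  connectivity
}
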