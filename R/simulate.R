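#' Assemble a thalamocortical network
#'
#' Bundles population sizes, per-population cell parameters and the
#' connectivity map into a network object consumed by
#' [simulate_network()].
#'
#' @param populations named sizes (`PY`, `IN`, `TC`, `RE`); defaults
#'   500/100/100/100.
#' @param connectivity a [build_connectivity()] map (built from
#'   `populations` by default).
#' @param cells named list of [cell_params()] per population.
#' @param overrides named list of per-cell-kind parameter overrides, e.g.
#'   `list(TC = list(G_KL = 0.9 * 0.024))`.
#' @return list of class `tc_network`.
#' @export
tc_network <- function(populations = c(PY = 500, IN = 100, TC = 100, RE = 100),
                       connectivity = NULL, cells = NULL, overrides = NULL) {
  if (is.null(connectivity)) connectivity <- build_connectivity(populations)
  if (is.null(cells))
    cells <- list(PY = cell_params("PY"), IN = cell_params("IN"),
                  TC = cell_params("TC"), RE = cell_params("RE"))
  if (!is.null(overrides))
    for (k in names(overrides))
      cells[[k]] <- do.call(cell_params, c(list(kind = k), overrides[[k]]))
  structure(list(populations = populations, connectivity = connectivity,
                 cells = cells),
            class = "tc_network")
}

#' Sequence stimulation protocol
#'
#' Defines the trained sequence geometry: `n_groups` contiguous groups of
#' `group_size` neurons starting at `start`, activated in the order given
#' by `order` with a 10 ms pulse per group and a 5 ms delay between
#' subsequent activations (so group onsets are 15 ms apart). In test mode
#' only the first group of `order` is stimulated and the response is read
#' in a 350 ms window ("pattern completion").
#'
#' @param start first neuron index (1-based; default 200).
#' @param group_size neurons per group (default 5; 2 for non-linear
#'   sequences).
#' @param n_groups number of groups (default 5).
#' @param order activation order over group labels (default `A`-`E`;
#'   e.g. `c("A","C","B","D","E")` for a non-linear sequence).
#' @param direction +1 to lay out groups towards increasing indices, -1
#'   decreasing.
#' @param pulse_ms stimulation pulse duration (default 10).
#' @param gap_ms delay between subsequent group activations (default 5).
#' @param period_ms trial period (default 1000).
#' @param amplitude injected current density (uA/cm2) during the pulse.
#' @param response_ms recall response window (default 350).
#' @return list of class `stim_protocol` with a `groups` element (named
#'   list of neuron indices).
#' @export
stim_protocol <- function(start = 200, group_size = 5, n_groups = 5,
                          order = LETTERS[1:5], direction = 1,
                          pulse_ms = 10, gap_ms = 5, period_ms = 1000,
                          amplitude = 8, response_ms = 350) {
  labels <- LETTERS[seq_len(n_groups)]
  stopifnot(all(order %in% labels))
  idx <- start + direction * (0:(group_size * n_groups - 1))
  groups <- split(idx, rep(seq_len(n_groups), each = group_size))
  names(groups) <- labels
  structure(list(start = start, group_size = group_size,
                 n_groups = n_groups, order = order, direction = direction,
                 pulse_ms = pulse_ms, gap_ms = gap_ms,
                 period_ms = period_ms, amplitude = amplitude,
                 response_ms = response_ms, groups = groups),
            class = "stim_protocol")
}

#' Stimulus events for a training or test session
#'
#' Expands a protocol into per-neuron current pulses. In `train` mode all
#' groups are activated in protocol order (onsets 0, 15, 30, ... ms within
#' the trial); in `test` mode only the first group of the order receives
#' input ("pattern completion").
#'
#' @param protocol a [stim_protocol()].
#' @param mode `"train"` or `"test"`.
#' @param t_start session start (ms).
#' @param n_trials number of 1 s trials.
#' @return data.frame `neuron`, `t_on`, `t_off`, `amp` with attribute
#'   `onsets` (trial onset times).
#' @export
stim_events <- function(protocol, mode = c("train", "test"), t_start,
                        n_trials) {
  mode <- match.arg(mode)
  ord <- if (mode == "train") protocol$order else protocol$order[1]
  step <- protocol$pulse_ms + protocol$gap_ms
  onsets <- t_start + (seq_len(n_trials) - 1) * protocol$period_ms
  rows <- list()
  for (k in seq_along(onsets)) {
    for (g in seq_along(ord)) {
      neurons <- protocol$groups[[ord[g]]]
      t_on <- onsets[k] + (g - 1) * step
      rows[[length(rows) + 1L]] <- data.frame(
        neuron = neurons, t_on = t_on, t_off = t_on + protocol$pulse_ms,
        amp = protocol$amplitude)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "onsets") <- onsets
  out
}

#' Simulate the network over a stage schedule
#'
#' Integrates the full network with fixed-step RK4 (default dt = 0.02 ms).
#' Spikes are registered on upward zero crossings of the axosomatic
#' (cortical) or membrane (thalamic) voltage with a 2 ms refractory;
#' miniature PSPs are drawn from their time-dependent Poisson processes;
#' STDP is applied at spike times on the plastic cortical projection;
#' stage boundaries instantaneously swap the neuromodulator and plasticity
#' parameters.
#'
#' @param net a [tc_network()].
#' @param schedule data.frame with columns `stage`
#'   (`"awake"`/`"n2"`/`"n3"`) and `duration` (ms). A zero-row or
#'   zero-duration schedule returns an empty record.
#' @param sessions list of session descriptors:
#'   `list(protocol =, mode = "train"|"test", t_start =, n_trials =)`.
#'   Sessions must lie inside the schedule.
#' @param seed integer RNG seed (initial-state jitter and minis).
#' @param dt integration step, ms.
#' @param lfp_dt LFP sampling interval, ms (default 0.5 = 2 kHz).
#' @param snapshot_ms weight-snapshot interval (0 disables).
#' @param plastic,minis master switches.
#' @param scale_minis if TRUE (default) mini amplitudes are scaled by the
#'   stage AMPA/GABA factor of their projection relative to the awake
#'   factor, treating minis as receptor events like evoked PSPs.
#' @param background_hz per-cell rate (Hz) of sparse suprathreshold
#'   background barrages onto pyramidal cells, modelling afferents from
#'   cortex outside the simulated patch. One event excites a contiguous
#'   group of `2*background_radius + 1` cells through the same decaying
#'   AMPA conductance as the minis; whether the group recruits its
#'   neighbours is decided by the stage synaptic factors.
#' @param background_mv amplitude of one background input, as the PSP
#'   size in mV it would produce at rest (suprathreshold by design).
#' @param background_radius half-width of a barrage in neurons
#'   (default 8).
#' @param v_jitter initial-voltage jitter half-range, mV.
#' @param record_v optional matrix (pop, neuron 1-based) of cells whose
#'   voltage to record at the LFP rate.
#' @return a `tc_record`: list with `raster` (PY [spike_raster()]),
#'   `spikes` (all populations), `lfp`, `lfp_fs`, `weight_times`,
#'   `weights` (snapshot matrix), `synapses` (plastic synapse table),
#'   `final_weights`, `stages`, `sessions`, `seed`.
#' @export
simulate_network <- function(net, schedule, sessions = list(), seed = 1,
                             dt = 0.02, lfp_dt = 0.5, snapshot_ms = 5000,
                             plastic = TRUE, minis = TRUE,
                             scale_minis = TRUE, background_hz = 0.4,
                             background_mv = 30, background_radius = 8,
                             v_jitter = 2, record_v = NULL) {
  stopifnot(inherits(net, "tc_network"))
  if (!nrow(schedule) || sum(schedule$duration) <= 0)
    return(empty_record(net, seed))
  if (any(schedule$duration <= 0)) stop("stage durations must be > 0")
  stages_used <- unique(tolower(schedule$stage))
  bundles <- lapply(stages_used, stage_params)
  t_end <- cumsum(schedule$duration)
  t_total <- t_end[length(t_end)]
  sched <- cbind(match(tolower(schedule$stage), stages_used) - 1L, t_end)

  stage_list <- lapply(bundles, function(b) list(
    gkl = unname(b$ach_gkl[c("PY", "IN", "TC", "RE")]),
    ha_gh = b$ha_gh,
    A_plus = b$stdp$A_plus, A_minus = b$stdp$A_minus,
    tau_plus = b$stdp$tau_plus, tau_minus = b$stdp$tau_minus,
    f = b$stdp$f, bound = b$stdp$bound_frac))

  pops <- c("PY", "IN", "TC", "RE")
  cm <- net$connectivity
  projections <- list()
  for (pn in names(cm$projections)) {
    syn <- cm$projections[[pn]]
    if (!nrow(syn)) next
    src <- sub("->.*", "", pn)
    tgt <- sub("/.*", "", sub(".*->", "", pn))
    rec <- sub(".*/", "", pn)
    factor <- vapply(bundles, function(b) stage_synaptic_factor(pn, b),
                     numeric(1))
    projections[[length(projections) + 1L]] <- list(
      name = pn,
      src = match(src, pops) - 1L, tgt = match(tgt, pops) - 1L,
      rec = match(rec, c("AMPA", "NMDA", "GABAA", "GABAB")) - 1L,
      pre = syn$pre - 1L, post = syn$post - 1L,
      w = syn$weight,
      ma = if ("mini_amp" %in% names(syn)) syn$mini_amp else NULL,
      factor = factor,
      mini = "mini_amp" %in% names(syn),
      mini_conv = mini_conversion(net$cells[[tgt]], rec),
      mini_factor = if (scale_minis)
        factor / stage_synaptic_factor(pn, "awake") else
        rep(1, length(factor)),
      stdp = pn == "PY->PY/AMPA")
  }

  # stimulus events
  stim <- matrix(numeric(0), 0, 5)
  session_meta <- list()
  for (ss in sessions) {
    ev <- stim_events(ss$protocol, ss$mode, ss$t_start, ss$n_trials)
    if (min(ev$t_on) < 0 || max(ev$t_off) > t_total)
      stop("session lies outside the schedule window")
    if (any(ev$neuron < 1 | ev$neuron > net$populations[["PY"]]))
      stop("stimulated group indices fall outside the network")
    stim <- rbind(stim, cbind(0, ev$neuron - 1L, ev$t_on, ev$t_off, ev$amp))
    session_meta[[length(session_meta) + 1L]] <-
      list(mode = ss$mode, protocol = ss$protocol,
           onsets = attr(ev, "onsets"))
  }


  cfg <- list(
    pops = lapply(net$cells, unclass),
    n = as.integer(net$populations[pops]),
    stages = stage_list, schedule = sched,
    projections = projections,
    stim = stim,
    dt = dt, t_total = t_total,
    lfp_every = as.integer(round(lfp_dt / dt)),
    snap_ms = snapshot_ms,
    stdp_gmax = cm$weights[["PY->PY/AMPA"]],
    mini_ref_amp = 0.2,
    plastic = plastic, minis = minis,
    bg_rate = background_hz,
    bg_amp = background_mv * mini_conversion(net$cells$PY, "AMPA"),
    bg_radius = as.integer(background_radius),
    v0 = c(net$cells$PY$E_L, net$cells$IN$E_L,
           net$cells$TC$E_L, net$cells$RE$E_L),
    v_jitter = v_jitter,
    vrec = if (is.null(record_v)) NULL else
      cbind(record_v[, 1], record_v[, 2] - 1L))

  set.seed(seed)
  raw <- .sim_run(cfg)

  spikes <- data.frame(pop = pops[raw$spike_pop + 1L],
                       neuron = raw$spike_idx, time = raw$spike_t)
  py <- spikes[spikes$pop == "PY", ]
  record <- list(
    raster = spike_raster(py$neuron, py$time,
                          n_neurons = net$populations[["PY"]],
                          t_max = t_total),
    spikes = spikes,
    lfp = raw$lfp, lfp_fs = 1000 / (dt * cfg$lfp_every),
    weight_times = raw$snap_t, weights = raw$snapshots,
    synapses = cm$projections[["PY->PY/AMPA"]][, c("pre", "post")],
    final_weights = raw$weights, final_mini_amps = raw$mini_amps,
    vrec = raw$vrec,
    stages = data.frame(stage = tolower(schedule$stage),
                        onset = c(0, utils::head(t_end, -1)),
                        offset = t_end),
    sessions = session_meta, seed = seed, net = net)
  class(record) <- "tc_record"
  record
}

# Conversion from a PSP amplitude in mV to the instantaneous synaptic
# conductance increment (uS) that produces it on the target dendrite.
# Because the receptor decay is much faster than the membrane time
# constant, the peak depolarization is charge-dominated:
# dV ~ dg * drive * tau_syn / C, so dg = A * C / (drive * tau_syn).
# The driving force is evaluated at the resting potential (floored at
# 10 mV for receptors reversing near rest).
mini_conversion <- function(cell, receptor, gain = mini_gain()) {
  tau_syn <- 1 / switch(receptor, AMPA = 0.19, GABAA = 0.18, 0.19)
  e_rev <- switch(receptor, AMPA = 0, GABAA = -70, 0)
  drive <- max(abs(e_rev - cell$E_L), 10)
  dens <- gain * cell$C_m / (drive * tau_syn)       # mS/cm2 per mV
  dens * cell$rho * cell$S_soma * 1000              # uS per mV
}

# Effective gain of the PSP-amplitude conversion. The stated mini
# amplitude is mapped to a conductance increment through the local input
# resistance of the dendritic compartment; the gain absorbs the
# difference between the isolated-compartment estimate and the in-vivo
# like effective resistance, and is calibrated once so that the awake
# network reproduces its characteristic background firing rate with the
# default 0.2 mV amplitude.
mini_gain <- function() getOption("tcsleep.mini_gain", 6)

empty_record <- function(net, seed) {
  structure(list(
    raster = spike_raster(integer(0), numeric(0),
                          n_neurons = net$populations[["PY"]], t_max = 0),
    spikes = data.frame(pop = character(0), neuron = integer(0),
                        time = numeric(0)),
    lfp = numeric(0), lfp_fs = NA_real_,
    weight_times = numeric(0), weights = matrix(numeric(0), 0, 0),
    synapses = net$connectivity$projections[["PY->PY/AMPA"]][, c("pre", "post")],
    final_weights = list(), final_mini_amps = list(), vrec = list(),
    stages = data.frame(stage = character(0), onset = numeric(0),
                        offset = numeric(0)),
    sessions = list(), seed = seed, net = net), class = "tc_record")
}

#' @export
print.tc_record <- function(x, ...) {
  cat("<tc_record>\n")
  cat(sprintf("  %d spikes / %d PY neurons / %.1f s\n",
              nrow(x$spikes), attr(x$raster, "n_neurons"),
              attr(x$raster, "t_max") / 1000))
  if (nrow(x$stages))
    cat("  stages:", paste(sprintf("%s(%.0fs)", x$stages$stage,
        (x$stages$offset - x$stages$onset) / 1000), collapse = " -> "), "\n")
  invisible(x)
}

#' @export
plot.tc_record <- function(x, t_range = NULL, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(op))
  r <- if (is.null(t_range)) x$raster else raster_window(x$raster, t_range)
  plot(r, ...)
  if (length(x$lfp)) {
    tt <- (seq_along(x$lfp) - 1) / x$lfp_fs * 1000
    sel <- if (is.null(t_range)) rep(TRUE, length(tt)) else
      tt >= t_range[1] & tt < t_range[2]
    graphics::plot(tt[sel], x$lfp[sel], type = "l", xlab = "time (ms)",
                   ylab = "LFP (mV)")
  }
  invisible(x)
}

#' Persist / load a simulation record (plain-text container)
#'
#' Writes the raster as TSV, the LFP and weight snapshots as CSV and the
#' metadata as JSON into a directory.
#'
#' @param record a `tc_record`.
#' @param dir target directory (created if needed).
#' @return `save_record` returns `dir` invisibly; `load_record` returns a
#'   `tc_record` (without the network object).
#' @export
save_record <- function(record, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_raster(record$raster, file.path(dir, "raster.tsv"))
  utils::write.csv(data.frame(lfp = record$lfp),
                   file.path(dir, "lfp.csv"), row.names = FALSE)
  if (length(record$weight_times)) {
    w <- as.data.frame(record$weights)
    w$time <- record$weight_times
    utils::write.csv(w, file.path(dir, "weights.csv"), row.names = FALSE)
  }
  meta <- list(lfp_fs = record$lfp_fs, seed = record$seed,
               stages = record$stages)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname save_record
#' @export
load_record <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  rec <- list(raster = read_raster(file.path(dir, "raster.tsv")),
              lfp = utils::read.csv(file.path(dir, "lfp.csv"))$lfp,
              lfp_fs = meta$lfp_fs, seed = meta$seed,
              stages = as.data.frame(meta$stages))
  wf <- file.path(dir, "weights.csv")
  if (file.exists(wf)) {
    w <- utils::read.csv(wf)
    rec$weight_times <- w$time
    rec$weights <- as.matrix(w[, setdiff(names(w), "time"), drop = FALSE])
  }
  class(rec) <- "tc_record"
  rec
}
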