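#' Mask of cortical synapses oriented along a trained sequence
#'
#' Selects the plastic PY-to-PY AMPA synapses whose presynaptic and
#' postsynaptic neurons both belong to a trained chain and whose direction
#' agrees with the order of training (presynaptic neuron earlier in the
#' chain than the postsynaptic one). The mean weight over this mask is the
#' memory-strength measure tracked across sleep.
#'
#' @param connectivity a [build_connectivity()] map.
#' @param neurons ordered integer vector of trained neurons (1-based, in
#'   training order; decreasing for a sequence trained towards lower
#'   indices).
#' @param backward if TRUE, select the opposite orientation instead.
#' @return logical vector over the rows of the PY-PY AMPA synapse table.
#' @export
sequence_weight_mask <- function(connectivity, neurons, backward = FALSE) {
  syn <- connectivity$projections[["PY->PY/AMPA"]]
  if (is.null(syn)) stop("connectivity map has no PY->PY/AMPA projection")
  pos_pre <- match(syn$pre, neurons)
  pos_post <- match(syn$post, neurons)
  ok <- !is.na(pos_pre) & !is.na(pos_post)
  if (backward) ok & (pos_post < pos_pre) else ok & (pos_post > pos_pre)
}

#' Relative mean-weight trajectory over a synapse mask
#'
#' @param times numeric vector of snapshot times (ms).
#' @param weights matrix of synaptic weights, one row per snapshot, one
#'   column per synapse.
#' @param mask logical or integer selection of synapses.
#' @param reference weights used as the 100% baseline; defaults to the
#'   first snapshot row.
#' @return data.frame with `time` and `mean_rel_change` (mean over the mask
#'   of `w / w_ref - 1`).
#' @export
weight_trajectory <- function(times, weights, mask, reference = NULL) {
  stopifnot(length(times) == nrow(weights))
  w <- weights[, mask, drop = FALSE]
  if (!ncol(w)) stop("empty synapse mask")
  ref <- if (is.null(reference)) w[1, ] else reference[mask]
  ref[ref == 0] <- NA
  data.frame(time = times,
             mean_rel_change = rowMeans(sweep(w, 2, ref, "/") - 1,
                                        na.rm = TRUE))
}

#' Probability of successful consolidation across replicates
#'
#' A replicate counts as successfully consolidated when the linear trend of
#' its mask-mean synaptic weight over the final `window` ms of sleep is
#' positive. The probability is the fraction of replicates with a positive
#' trend.
#'
#' @param trajectories list of data.frames as returned by
#'   [weight_trajectory()].
#' @param window trend window in ms counted back from the last snapshot
#'   (default 1e5 = 100 s).
#' @return list with `probability` and per-replicate `slopes`
#'   (change per second).
#' @export
consolidation_probability <- function(trajectories, window = 1e5) {
  slopes <- vapply(trajectories, function(tr) {
    sel <- tr$time >= max(tr$time) - window
    if (sum(sel) < 2) stop("fewer than 2 snapshots in the trend window")
    1000 * unname(stats::coef(stats::lm(mean_rel_change ~ time,
                                        data = tr[sel, ]))[2])
  }, numeric(1))
  list(probability = mean(slopes > 1e-10), slopes = slopes)
}

#' Recall-performance change at untrained network locations
#'
#' Scores virtual sequences (contiguous groups analogous to the trained
#' ones) at arbitrary chain locations and directions in two test sessions,
#' and reports the after-minus-before performance difference per location.
#' Locations overlapping the trained span are flagged rather than silently
#' included.
#'
#' @param raster_before,raster_after [spike_raster()]s of the two test
#'   sessions (before training, after sleep).
#' @param onsets_before,onsets_after stimulus-onset times in each session.
#' @param locations integer vector of start neurons for the virtual
#'   sequences.
#' @param directions subset of `c(1, -1)`: increasing and/or decreasing
#'   neuron indices.
#' @param group_size,n_groups virtual sequence geometry (defaults 5 and 5).
#' @param trained_span integer range of the actually trained neurons, used
#'   only for flagging.
#' @param th success threshold passed to [recall_performance()].
#' @return data.frame: `location`, `direction`, `perf_before`,
#'   `perf_after`, `diff`, `overlaps_trained`.
#' @export
untrained_location_scan <- function(raster_before, raster_after,
                                    onsets_before, onsets_after,
                                    locations, directions = c(1, -1),
                                    group_size = 5, n_groups = 5,
                                    trained_span = NULL, th = 0.8) {
  n <- attr(raster_before, "n_neurons")
  rows <- list()
  for (loc in locations) for (dir in directions) {
    idx <- loc + dir * (0:(group_size * n_groups - 1))
    if (min(idx) < 1 || max(idx) > n) next
    groups <- split(idx, rep(seq_len(n_groups), each = group_size))
    names(groups) <- LETTERS[seq_len(n_groups)]
    pb <- recall_performance(
      score_session(raster_before, groups, onsets_before)$sm, th = th)
    pa <- recall_performance(
      score_session(raster_after, groups, onsets_after)$sm, th = th)
    rows[[length(rows) + 1L]] <- data.frame(
      location = loc, direction = dir, perf_before = pb, perf_after = pa,
      diff = pa - pb,
      overlaps_trained = !is.null(trained_span) &&
        any(idx %in% trained_span))
  }
  do.call(rbind, rows)
}
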