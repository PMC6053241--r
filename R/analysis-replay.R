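#' Count sequence replays in a sleep raster
#'
#' Detects spontaneous replays of a trained sequence inside a region of the
#' cortical chain by spike chaining, following the five-step procedure:
#' (i) every spike of the leading neuron of the region seeds one candidate
#' replay; (ii) for each subsequent neuron along the chain the spike closest
#' in time to the current anchor is taken; (iii) if the closest spike is
#' more than `max_gap` ms away it is rejected and the previous anchor is
#' carried forward; (iv) each consecutive block of `group_size` neurons is
#' summarized by the mean of its accepted spike times; (v) the groups are
#' ordered by those mean times and the order is scored against the trained
#' sequence with [string_match()]. A candidate counts as a correct (reverse)
#' replay when the score against the trained (mirrored) order reaches `th`.
#'
#' @param raster a [spike_raster()] (spontaneous activity, e.g. one sleep
#'   epoch).
#' @param neurons integer vector: the ordered chain of trained neurons
#'   (25 for a five-group sequence). The first element is the leading
#'   neuron; pass a decreasing vector for a sequence trained in the
#'   direction of decreasing indices.
#' @param group_size neurons per group (default 5).
#' @param th string-match success threshold (default 0.8).
#' @param max_gap chaining rejection threshold in ms (default 50).
#' @return list with `n_candidates` (leading-neuron spikes), `correct`,
#'   `reverse` (replay counts), `fraction_correct` (correct / candidates;
#'   `NaN` when there are no candidates), `fraction_correct_of_detected`
#'   (correct / (correct + reverse)), and `scores` (per-candidate
#'   data.frame with forward and reverse scores).
#' @export
detect_replays <- function(raster, neurons, group_size = 5, th = 0.8,
                           max_gap = 50) {
  n <- length(neurons)
  stopifnot(n %% group_size == 0)
  n_groups <- n %/% group_size
  labels <- LETTERS[seq_len(n_groups)]
  spk <- split(raster$time, factor(raster$neuron, levels = neurons))
  lead <- spk[[1]]
  if (!length(lead))
    return(replay_result(0L, 0L, 0L, data.frame()))
  rows <- vector("list", length(lead))
  for (m in seq_along(lead)) {
    t_chain <- rep(NA_real_, n)
    t_chain[1] <- anchor <- lead[m]
    for (k in 2:n) {
      tk <- spk[[k]]
      if (length(tk)) {
        j <- which.min(abs(tk - anchor))
        if (abs(tk[j] - anchor) <= max_gap) {
          t_chain[k] <- tk[j]
          anchor <- tk[j]
        }
      }
    }
    grp <- rep(seq_len(n_groups), each = group_size)
    t_grp <- tapply(t_chain, grp, function(x) mean(x, na.rm = TRUE))
    present <- is.finite(t_grp)
    seq_det <- labels[present][order(t_grp[present])]
    sm_fwd <- string_match(seq_det, labels)
    sm_rev <- string_match(seq_det, rev(labels))
    rows[[m]] <- data.frame(t = lead[m], sm_forward = sm_fwd,
                            sm_reverse = sm_rev)
  }
  scores <- do.call(rbind, rows)
  replay_result(length(lead),
                sum(scores$sm_forward >= th),
                sum(scores$sm_reverse >= th),
                scores)
}

replay_result <- function(n_cand, correct, reverse, scores) {
  list(n_candidates = n_cand, correct = correct, reverse = reverse,
       fraction_correct = if (n_cand) correct / n_cand else NaN,
       fraction_correct_of_detected =
         if (correct + reverse) correct / (correct + reverse) else NaN,
       scores = scores)
}

#' Replay counts restricted to detected sleep events
#'
#' Runs [detect_replays()] inside each event epoch (spindles during N2, Up
#' states during N3) and totals the counts. The per-epoch denominator and
#' the per-leading-spike denominator are both reported.
#'
#' @param raster a [spike_raster()].
#' @param events data.frame with `onset`/`offset` columns in ms (as returned
#'   by [detect_sleep_events()]).
#' @param neurons ordered trained chain (see [detect_replays()]).
#' @param ... passed to [detect_replays()].
#' @return list with total `correct`, `reverse`, `n_candidates`,
#'   `n_epochs`, `per_epoch` data.frame, and the two fractions.
#' @export
count_replays_in_events <- function(raster, events, neurons, ...) {
  if (!nrow(events)) {
    return(list(correct = 0L, reverse = 0L, n_candidates = 0L, n_epochs = 0L,
                per_epoch = data.frame(), fraction_correct = NaN,
                fraction_correct_of_detected = NaN))
  }
  per <- lapply(seq_len(nrow(events)), function(i) {
    w <- raster_window(raster, t_range = c(events$onset[i], events$offset[i]))
    r <- detect_replays(w, neurons, ...)
    data.frame(onset = events$onset[i], offset = events$offset[i],
               n_candidates = r$n_candidates, correct = r$correct,
               reverse = r$reverse)
  })
  per <- do.call(rbind, per)
  tot_c <- sum(per$correct); tot_r <- sum(per$reverse)
  n_cand <- sum(per$n_candidates)
  list(correct = tot_c, reverse = tot_r, n_candidates = n_cand,
       n_epochs = nrow(events), per_epoch = per,
       fraction_correct = if (n_cand) tot_c / n_cand else NaN,
       fraction_correct_of_detected =
         if (tot_c + tot_r) tot_c / (tot_c + tot_r) else NaN)
}
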