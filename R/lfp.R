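#' Band-filtered network LFP
#'
#' The network LFP is defined as the mean dendritic membrane voltage of the
#' pyramidal population, zero-phase band-pass filtered (2nd-order
#' Butterworth applied forward and backward).
#'
#' @param x numeric vector: raw LFP samples (mV), or a `tc_record` whose
#'   `lfp` field is used.
#' @param fs sampling rate in Hz (taken from the record if `x` is one).
#' @param band numeric length-2 pass band in Hz; default `c(0.1, 100)`
#'   (broadband).
#' @return numeric vector of filtered samples.
#' @export
compute_lfp <- function(x, fs = NULL, band = c(0.1, 100)) {
  if (inherits(x, "tc_record")) {
    fs <- x$lfp_fs
    x <- x$lfp
  }
  stopifnot(!is.null(fs), length(band) == 2, band[1] >= 0, band[1] < band[2])
  if (band[2] >= fs / 2)
    stop("band upper edge must be below the Nyquist frequency ", fs / 2, " Hz")
  if (band[1] <= 0) {
    flt <- signal::butter(2, band[2] / (fs / 2), type = "low")
    as.numeric(signal::filtfilt(flt, x - mean(x)))
  } else {
    flt <- signal::butter(2, band / (fs / 2), type = "pass")
    as.numeric(signal::filtfilt(flt, x - mean(x)))
  }
}

#' Detect sleep events (spindles or Up/Down states)
#'
#' Spindles are detected from the 7-14 Hz LFP envelope: epochs where the
#' envelope exceeds `mean + k*sd` (expanded to the surrounding
#' `mean + 0.5*sd` crossings), lasting 0.3-3.5 s, with epochs closer than
#' 250 ms merged. Up states are detected from the smoothed pyramidal
#' population firing rate crossing a fraction of its 95th percentile
#' (default 0.5: an Up state of the slow oscillation engages a large part
#' of the population, so only strong network-wide rate excursions
#' qualify); Down states are the complementary intervals. Each event also
#' reports its initiation site, the neuron spiking earliest in the
#' event.
#'
#' @param record a `tc_record` (or a list with `lfp`, `lfp_fs`, `raster`).
#' @param stage `"n2"` (returns spindles) or `"n3"` (returns Up states).
#' @param t_range restrict detection to this window (ms).
#' @param ... passed on to [detect_spindles()] or [detect_upstates()].
#' @return data.frame with `onset`, `offset` (ms), `duration`,
#'   `initiation_site`; zero rows when nothing is detected.
#' @export
detect_sleep_events <- function(record, stage, t_range = NULL, ...) {
  stage <- match.arg(tolower(stage), c("n2", "n3", "awake"))
  ev <- switch(stage,
    n2 = detect_spindles(record$lfp, record$lfp_fs, t_range = t_range, ...),
    n3 = detect_upstates(record$raster, t_range = t_range, ...),
    awake = empty_events())
  ev$initiation_site <- vapply(seq_len(nrow(ev)), function(i) {
    w <- raster_window(record$raster, c(ev$onset[i], ev$offset[i]))
    if (!nrow(w)) return(NA_integer_)
    w$neuron[which.min(w$time)]
  }, integer(1))
  ev
}

empty_events <- function() {
  data.frame(onset = numeric(0), offset = numeric(0), duration = numeric(0))
}

#' @rdname detect_sleep_events
#' @param lfp raw LFP vector (mV).
#' @param fs LFP sampling rate (Hz).
#' @param band spindle band in Hz.
#' @param k envelope threshold in sd units above the mean.
#' @param min_dur,max_dur admissible epoch durations (ms).
#' @export
detect_spindles <- function(lfp, fs, t_range = NULL, band = c(7, 14),
                            k = 2, min_dur = 300, max_dur = 3500) {
  t_ms <- (seq_along(lfp) - 1L) / fs * 1000
  if (!is.null(t_range)) {
    sel <- t_ms >= t_range[1] & t_ms < t_range[2]
    lfp <- lfp[sel]; t_ms <- t_ms[sel]
  }
  if (length(lfp) < fs) return(empty_events())
  bp <- compute_lfp(lfp, fs, band = band)
  win <- max(1L, round(0.1 * fs))            # 100 ms RMS window
  env <- sqrt(stats::filter(bp^2, rep(1 / win, win), sides = 2))
  env[is.na(env)] <- 0
  hi <- mean(env) + k * stats::sd(env)
  lo <- mean(env) + 0.5 * stats::sd(env)
  ev <- threshold_epochs(as.numeric(env), t_ms, hi, lo)
  ev <- merge_epochs(ev, gap = 250)
  ev[ev$duration >= min_dur & ev$duration <= max_dur, , drop = FALSE]
}

#' @rdname detect_sleep_events
#' @param raster a [spike_raster()] of the pyramidal population.
#' @param frac threshold as a fraction of the 95th percentile of the
#'   smoothed population rate.
#' @export
detect_upstates <- function(raster, t_range = NULL, frac = 0.5,
                            min_dur = 100) {
  if (is.null(t_range)) t_range <- c(0, attr(raster, "t_max"))
  bin <- 10
  edges <- seq(t_range[1], t_range[2], by = bin)
  if (length(edges) < 20) return(empty_events())
  sel <- raster$time >= t_range[1] & raster$time < t_range[2]
  counts <- tabulate(floor((raster$time[sel] - t_range[1]) / bin) + 1L,
                     nbins = length(edges) - 1L)
  kern <- rep(1 / 5, 5)                      # 50 ms smoothing
  rate <- as.numeric(stats::filter(counts, kern, sides = 2))
  rate[is.na(rate)] <- 0
  thr <- frac * stats::quantile(rate, 0.95, names = FALSE)
  if (thr <= 0) return(empty_events())
  t_mid <- edges[-length(edges)] + bin / 2
  ev <- threshold_epochs(rate, t_mid, thr, thr)
  ev <- merge_epochs(ev, gap = 50)
  ev[ev$duration >= min_dur, , drop = FALSE]
}

# Hysteresis thresholding of a 1-D signal: epochs where x exceeds `hi`,
# expanded outward to the surrounding `lo` crossings.
threshold_epochs <- function(x, t, hi, lo) {
  above_hi <- x >= hi
  if (!any(above_hi)) return(empty_events())
  above_lo <- x >= lo
  r <- rle(above_lo)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & vapply(seq_along(r$values), function(i)
    r$values[i] && any(above_hi[starts[i]:ends[i]]), logical(1))
  if (!any(keep)) return(empty_events())
  data.frame(onset = t[starts[keep]], offset = t[ends[keep]],
             duration = t[ends[keep]] - t[starts[keep]])
}

merge_epochs <- function(ev, gap) {
  if (nrow(ev) < 2) return(ev)
  out <- ev[1, , drop = FALSE]
  for (i in 2:nrow(ev)) {
    if (ev$onset[i] - out$offset[nrow(out)] < gap) {
      out$offset[nrow(out)] <- ev$offset[i]
    } else out <- rbind(out, ev[i, ])
  }
  out$duration <- out$offset - out$onset
  rownames(out) <- NULL
  out
}

#' Stage summary statistics
#'
#' Convenience measures used to characterize the three stages: mean
#' pyramidal firing rate (Hz), spindle density (events per minute) and
#' slow-oscillation frequency (Up states per second).
#'
#' @param record a `tc_record`.
#' @param t_range window in ms.
#' @return named list `rate_hz`, `spindle_per_min`, `so_hz`.
#' @export
stage_statistics <- function(record, t_range = NULL) {
  r <- record$raster
  if (is.null(t_range)) t_range <- c(0, attr(r, "t_max"))
  dur_s <- (t_range[2] - t_range[1]) / 1000
  nspk <- sum(r$time >= t_range[1] & r$time < t_range[2])
  sp <- detect_spindles(record$lfp, record$lfp_fs, t_range = t_range)
  up <- detect_upstates(r, t_range = t_range)
  list(rate_hz = nspk / attr(r, "n_neurons") / dur_s,
       spindle_per_min = nrow(sp) / (dur_s / 60),
       so_hz = nrow(up) / dur_s)
}
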