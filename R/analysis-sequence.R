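#' String-match similarity between a detected and an ideal sequence
#'
#' Measures how similar a recalled group-order sequence is to the trained
#' (ideal) one. With `S1` the detected sequence and `S` the ideal sequence,
#' let `S2` be the subsequence of `S` restricted to the elements present in
#' `S1`, and `N = length(S1)`. The raw score is
#' `SM = 2*N - sum_i |L(S1, S2[i]) - i|`, where `L(S1, x)` is the position
#' of element `x` within `S1`. The normalized score divides by
#' `M = 2 * length(S)`, so a perfect recall scores 1 and a fully reversed
#' recall of all elements scores negative. Detected elements not present in
#' the ideal alphabet are dropped, and repeated labels are collapsed to
#' their first occurrence before scoring.
#'
#' @param s1 detected sequence: character vector of labels, or a single
#'   string which is split into characters.
#' @param s ideal sequence, same conventions.
#' @param normalize if TRUE (default) divide by `2 * length(s)`.
#' @return a single numeric score; 0 for an empty detection.
#' @examples
#' string_match("ACDB", "ABCDE")   # 0.4
#' string_match("ABCDE", "ABCDE")  # 1.0
#' string_match("EDCBA", "ABCDE")  # -0.2
#' @export
string_match <- function(s1, s, normalize = TRUE) {
  s <- as_labels(s)
  if (!length(s)) stop("ideal sequence must be non-empty")
  if (anyDuplicated(s)) stop("ideal sequence must have unique labels")
  s1 <- as_labels(s1)
  s1 <- s1[!duplicated(s1)]
  s1 <- s1[s1 %in% s]
  if (!length(s1)) return(0)
  s2 <- s[s %in% s1]
  n <- length(s1)
  loc <- match(s2, s1)
  raw <- 2 * n - sum(abs(loc - seq_len(n)))
  if (normalize) raw / (2 * length(s)) else raw
}

as_labels <- function(x) {
  if (is.null(x)) return(character(0))
  x <- as.character(x)
  if (length(x) == 1L && nchar(x) != 1L) x <- strsplit(x, "")[[1]]
  x[nzchar(x)]
}

#' Detect the recalled group sequence in a response window
#'
#' Implements the recall-sequence read-out used on test trials: all spikes
#' of each trained group inside the response window are binned, the group
#' mean instantaneous firing rate is smoothed with a Gaussian kernel
#' (window 50 ms), and the groups are ordered by the peak time of their
#' smoothed rate. Groups that fire no spikes in the window are omitted.
#'
#' @param raster a [spike_raster()]; times relative to the stimulus onset.
#' @param groups named list of integer vectors: neuron indices per group
#'   label, e.g. `list(A = 200:204, B = 205:209, ...)` (1-based).
#' @param window response window in ms (default `c(0, 350)`).
#' @param kernel_window width of the Gaussian smoothing kernel in ms; the
#'   kernel standard deviation is `kernel_window / 4`.
#' @param bin rate bin in ms.
#' @return character vector of group labels in detected order.
#' @export
detect_recall_sequence <- function(raster, groups, window = c(0, 350),
                                   kernel_window = 50, bin = 1) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  times <- seq(window[1], window[2] - bin, by = bin) + bin / 2
  sigma <- kernel_window / 4
  half <- ceiling(2 * sigma / bin)
  kern <- stats::dnorm(seq(-half, half) * bin, sd = sigma)
  kern <- kern / sum(kern)
  peaks <- vapply(groups, function(idx) {
    sel <- raster$neuron %in% idx &
      raster$time >= window[1] & raster$time < window[2]
    if (!any(sel)) return(NA_real_)
    counts <- tabulate(floor((raster$time[sel] - window[1]) / bin) + 1L,
                       nbins = length(times))
    rate <- counts / (length(idx) * bin / 1000)
    sm <- stats::filter(c(rep(0, half), rate, rep(0, half)), kern, sides = 2)
    sm <- sm[(half + 1):(half + length(times))]
    times[which.max(sm)]
  }, numeric(1))
  names(sort(peaks[!is.na(peaks)]))
}

#' Recall performance over a test session
#'
#' Percentage of trials whose normalized string-match score reaches the
#' success threshold.
#'
#' @param scores numeric vector of normalized string-match scores, one per
#'   test trial.
#' @param th success threshold in (0, 1]; default 0.8 (at least 80%
#'   similarity counts as a successful recall).
#' @return percentage in \[0, 100\].
#' @examples
#' recall_performance(c(1.0, 0.4, 0.9), th = 0.8)  # 66.7%
#' @export
recall_performance <- function(scores, th = 0.8) {
  stopifnot(th > 0, th <= 1)
  if (!length(scores)) stop("no trials: cannot compute performance")
  100 * mean(scores >= th)
}

#' Score every test trial of a session
#'
#' Convenience wrapper: cuts a raster into fixed-period trials, runs
#' [detect_recall_sequence()] on each response window, and scores it
#' against the ideal sequence with [string_match()].
#'
#' @param raster a [spike_raster()] covering the session.
#' @param groups named list of neuron-index groups (see
#'   [detect_recall_sequence()]).
#' @param onsets numeric vector of stimulus-onset times in ms.
#' @param ideal ideal sequence (defaults to the group names in list order).
#' @param window response window relative to each onset.
#' @param ... passed to [detect_recall_sequence()].
#' @return data.frame with one row per trial: `onset`, `detected`
#'   (collapsed label string) and `sm` (normalized score).
#' @export
score_session <- function(raster, groups, onsets, ideal = names(groups),
                          window = c(0, 350), ...) {
  rows <- lapply(onsets, function(t0) {
    w <- raster_window(raster, t_range = t0 + window, rebase = TRUE)
    det <- detect_recall_sequence(w, groups, window = window - window[1], ...)
    data.frame(onset = t0, detected = paste(det, collapse = ""),
               sm = string_match(det, ideal))
  })
  do.call(rbind, rows)
}
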