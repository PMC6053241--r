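#' Spatial correlation of convolved spike trains versus distance
#'
#' For every neuron the spike train is convolved with a Gaussian kernel
#' (window 1000 ms, mean 500 ms, sd 5 ms). Within each event epoch
#' (a spindle or an Up state of the slow oscillation) the cross-correlation
#' of the convolved trains is computed for pairs of neurons at a given
#' chain distance, and the peak of the normalized cross-correlation
#' function (maximized over lags up to `max_lag`) is averaged over pairs
#' and epochs. Identical trains yield a peak of 1.
#'
#' @param raster a [spike_raster()].
#' @param events data.frame with `onset`/`offset` (ms) restricting the
#'   analysis to oscillation epochs; must be non-empty.
#' @param distances integer vector of neuron-pair distances to evaluate.
#' @param n_pairs maximal number of pairs sampled per distance (pairs are
#'   taken evenly spaced along the chain, so the estimate is deterministic).
#' @param bin rate bin in ms.
#' @param sigma_ms Gaussian kernel sd in ms (default 5).
#' @param max_lag cross-correlation lag range in ms (default 100).
#' @param pad_ms symmetric padding added to each epoch window (ms); use
#'   it to cover the full passage of a travelling wave whose
#'   population-rate detection is narrower than the wave itself.
#' @param normalize `"energy"` (default) normalizes by the signal
#'   energies without mean removal, the convention of the classic
#'   signal-processing cross-correlation (identical trains score 1, a
#'   silent/active pair 0); `"pearson"` removes the means first, so
#'   independent stationary trains decay to 0 with train length.
#' @return data.frame with columns `distance`, `mean_peak`, `sd_peak`,
#'   `n_pairs`.
#' @export
spatial_correlation <- function(raster, events, distances = NULL,
                                n_pairs = 30, bin = 1, sigma_ms = 5,
                                max_lag = 100, pad_ms = 0,
                                normalize = c("energy", "pearson")) {
  normalize <- match.arg(normalize)
  if (is.null(events) || !nrow(events))
    stop("event list is empty: spatial correlation is defined within epochs")
  events$onset <- events$onset - pad_ms
  events$offset <- events$offset + pad_ms
  n <- attr(raster, "n_neurons")
  if (is.null(distances)) distances <- unique(pmin(n - 1, c(1:10, seq(12, 150, by = 2))))
  half <- ceiling(500 / bin)            # 1000 ms kernel window
  kern <- stats::dnorm(seq(-half, half) * bin, sd = sigma_ms)
  kern <- kern / sum(kern)
  lag_bins <- ceiling(max_lag / bin)
  acc <- matrix(NA_real_, length(distances), 0)
  peaks <- vector("list", length(distances))
  for (e in seq_len(nrow(events))) {
    m <- raster_matrix(raster, bin = bin,
                       t_range = c(events$onset[e], events$offset[e]))
    if (ncol(m) < 4 * lag_bins) next
    sm <- t(apply(m, 1L, smooth1d, kern = kern))
    for (di in seq_along(distances)) {
      d <- distances[di]
      if (d >= n) next
      i1 <- seq(1L, n - d)
      if (length(i1) > n_pairs)
        i1 <- unique(round(seq(1L, n - d, length.out = n_pairs)))
      pk <- vapply(i1, function(i)
        xcorr_peak(sm[i, ], sm[i + d, ], lag_bins, normalize),
        numeric(1))
      peaks[[di]] <- c(peaks[[di]], pk[is.finite(pk)])
    }
  }
  data.frame(distance = distances,
             mean_peak = vapply(peaks, function(p) if (length(p)) mean(p) else NA_real_, 1),
             sd_peak = vapply(peaks, function(p) if (length(p) > 1) stats::sd(p) else NA_real_, 1),
             n_pairs = vapply(peaks, length, 1L))
}

smooth1d <- function(x, kern) {
  half <- (length(kern) - 1L) / 2L
  out <- stats::filter(c(rep(0, half), x, rep(0, half)), kern, sides = 2)
  as.numeric(out[(half + 1):(half + length(x))])
}

# Peak over lags |l| <= lag_bins of the normalized cross-correlation of
# x and y. A pair where one neuron is active and the other silent inside
# the epoch is maximally uncoordinated and scores 0; a pair where both
# are silent carries no information (NA, excluded).
xcorr_peak <- function(x, y, lag_bins, normalize = "energy") {
  if (normalize == "pearson") {
    sx <- stats::sd(x); sy <- stats::sd(y)
    if (sx == 0 && sy == 0) return(NA_real_)
    if (sx == 0 || sy == 0) return(0)
    cc <- stats::ccf(x, y, lag.max = lag_bins, plot = FALSE, demean = TRUE)
    return(max(cc$acf))
  }
  ex <- sum(x^2); ey <- sum(y^2)
  if (ex == 0 && ey == 0) return(NA_real_)
  if (ex == 0 || ey == 0) return(0)
  .xcorr_energy_peak(x, y, as.integer(lag_bins))
}

#' Large-distance plateau of the spatial correlation curve
#'
#' Summarizes a [spatial_correlation()] table by the mean peak correlation
#' over distances at or beyond `from`; this is the asymptotic level that
#' separates locally organized spindle activity (low plateau) from globally
#' coordinated slow-oscillation activity (high plateau).
#'
#' @param sc data.frame from [spatial_correlation()].
#' @param from smallest distance counted as "large" (default 50).
#' @return numeric plateau value.
#' @export
correlation_plateau <- function(sc, from = 50) {
  sel <- sc$distance >= from & is.finite(sc$mean_peak)
  if (!any(sel)) stop("no finite correlation estimates at distance >= ", from)
  mean(sc$mean_peak[sel])
}

#' Spatiotemporal cluster detection in a raster segment
#'
#' Bins a raster segment into a (neuron x time) activity matrix, smooths it
#' with a separable 2-D Gaussian kernel, binarizes at a fraction of the
#' segment maximum, and labels connected components (8-connectivity) of the
#' suprathreshold pixels. Each component is one cluster of coordinated
#' spiking. Clusters that co-occur in time and are separated by fewer than
#' `merge_dist` neurons (the monosynaptic radius) can additionally be
#' merged.
#'
#' @param raster a [spike_raster()].
#' @param t_range segment window in ms (one spindle or one slow-oscillation
#'   cycle); default the whole raster.
#' @param bin time bin in ms.
#' @param sigma_neurons,sigma_ms 2-D kernel sds (defaults 2 neurons,
#'   10 ms).
#' @param threshold fraction of the smoothed-segment maximum used for
#'   binarization (default 0.5).
#' @param merge_dist neuron separation below which temporally co-occurring
#'   clusters are merged (default 5).
#' @return list with `clusters` (data.frame: `id`, `n_neurons`, `n_pixels`,
#'   `neuron_min`, `neuron_max`, `t_on`, `t_off`), `merged` (same after
#'   merging), and `labels` (the integer label matrix).
#' @export
detect_clusters <- function(raster, t_range = NULL, bin = 2,
                            sigma_neurons = 2, sigma_ms = 10,
                            threshold = 0.5, merge_dist = 5) {
  m <- raster_matrix(raster, bin = bin, t_range = t_range)
  if (is.null(t_range)) t_range <- c(0, attr(raster, "t_max"))
  kn <- gauss_kernel(sigma_neurons, 1)
  kt <- gauss_kernel(sigma_ms, bin)
  sm <- apply(m, 2L, smooth1d, kern = kn)           # along neurons
  sm <- t(apply(sm, 1L, smooth1d, kern = kt))       # along time
  if (max(sm) <= 0)
    return(list(clusters = empty_clusters(), merged = empty_clusters(),
                labels = matrix(0L, nrow(m), ncol(m))))
  lab <- label_components(sm >= threshold * max(sm))
  cl <- summarize_clusters(lab, bin, t_range[1])
  merged_ids <- merge_cluster_ids(cl, merge_dist)
  ml <- lab
  ml[ml > 0L] <- merged_ids[ml[ml > 0L]]
  list(clusters = cl, merged = summarize_clusters(ml, bin, t_range[1]),
       labels = lab)
}

gauss_kernel <- function(sigma, step) {
  half <- max(1L, ceiling(3 * sigma / step))
  k <- stats::dnorm(seq(-half, half) * step, sd = sigma)
  k / sum(k)
}

empty_clusters <- function() {
  data.frame(id = integer(0), n_neurons = integer(0), n_pixels = integer(0),
             neuron_min = integer(0), neuron_max = integer(0),
             t_on = numeric(0), t_off = numeric(0))
}

summarize_clusters <- function(lab, bin, t0) {
  ids <- sort(unique(lab[lab > 0L]))
  if (!length(ids)) return(empty_clusters())
  rows <- lapply(ids, function(id) {
    w <- which(lab == id, arr.ind = TRUE)
    data.frame(id = id, n_neurons = length(unique(w[, 1])),
               n_pixels = nrow(w),
               neuron_min = min(w[, 1]), neuron_max = max(w[, 1]),
               t_on = t0 + (min(w[, 2]) - 1) * bin,
               t_off = t0 + max(w[, 2]) * bin)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Union-find over clusters: merge pairs that overlap in time and whose
# neuron ranges are separated by < merge_dist neurons. Returns, for each
# original cluster id, the id of its merged group (renumbered 1..k).
merge_cluster_ids <- function(cl, merge_dist) {
  k <- nrow(cl)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (k > 1) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      time_ov <- cl$t_on[i] < cl$t_off[j] && cl$t_on[j] < cl$t_off[i]
      gap <- max(cl$neuron_min[i], cl$neuron_min[j]) -
        min(cl$neuron_max[i], cl$neuron_max[j])
      if (time_ov && gap < merge_dist) parent[find(j)] <- find(i)
    }
  }
  roots <- vapply(seq_len(k), find, 1L)
  match(roots, unique(roots))
}
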