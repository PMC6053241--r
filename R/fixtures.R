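#' Synthetic spike raster with planted sequence activations
#'
#' Generates a raster emulating what the analysis chain consumes: ordered
#' group activations (each neuron of a group spikes once per activation,
#' groups separated by a fixed lag, spike times jittered), superimposed on
#' homogeneous Poisson background firing. This lets every analysis
#' operation be tested without running the network simulator.
#'
#' @param n_neurons population size (default 500).
#' @param duration raster duration in ms.
#' @param sequence character vector of group labels in activation order
#'   (default `LETTERS[1:5]`); labels index groups laid out contiguously
#'   from `start` in alphabetical order, so e.g. `c("A","C","B","D","E")`
#'   plants a non-linear order.
#' @param start first neuron of the planted span (1-based; default 200).
#' @param group_size neurons per group (default 5).
#' @param lag_ms inter-group activation lag (default 5 ms).
#' @param jitter_sd per-spike Gaussian jitter sd in ms (default 0).
#' @param background_hz homogeneous Poisson background rate per neuron
#'   (default 0).
#' @param activation_times onset times of the planted activations (ms);
#'   default a single activation at t = 10.
#' @param direction +1 to lay groups out towards increasing indices,
#'   -1 towards decreasing.
#' @param seed optional integer seed (uses and restores the RNG stream via
#'   a local seed when supplied).
#' @return a [spike_raster()] with attribute `groups`: the named list of
#'   neuron indices per group label.
#' @examples
#' r <- generate_fixture(duration = 400, jitter_sd = 1, background_hz = 1,
#'                       seed = 1)
#' detect_recall_sequence(r, attr(r, "groups"))
#' @export
generate_fixture <- function(n_neurons = 500, duration = 1000,
                             sequence = LETTERS[1:5], start = 200,
                             group_size = 5, lag_ms = 5, jitter_sd = 0,
                             background_hz = 0,
                             activation_times = 10, direction = 1,
                             seed = NULL) {
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  groups <- NULL
  if (length(activation_times)) {
    labels <- sort(unique(sequence))
    n_groups <- length(labels)
    idx_all <- start + direction * (0:(group_size * n_groups - 1))
    if (min(idx_all) < 1 || max(idx_all) > n_neurons)
      stop("planted span falls outside the population")
    groups <- split(idx_all, rep(seq_len(n_groups), each = group_size))
    names(groups) <- labels
    if (anyDuplicated(unlist(groups))) stop("planted groups overlap")
  }

  neuron <- integer(0); time <- numeric(0)
  for (t0 in activation_times) {
    for (k in seq_along(sequence)) {
      g <- groups[[sequence[k]]]
      tt <- rep(t0 + (k - 1) * lag_ms, length(g)) +
        if (jitter_sd > 0) stats::rnorm(length(g), sd = jitter_sd) else 0
      neuron <- c(neuron, g)
      time <- c(time, tt)
    }
  }
  if (background_hz > 0) {
    n_bg <- stats::rpois(1, background_hz * n_neurons * duration / 1000)
    neuron <- c(neuron, sample.int(n_neurons, n_bg, replace = TRUE))
    time <- c(time, stats::runif(n_bg, 0, duration))
  }
  keep <- time >= 0 & time < duration
  out <- spike_raster(neuron[keep], time[keep], n_neurons, t_max = duration)
  attr(out, "groups") <- groups
  out
}

#' Poisson raster at a fixed rate
#'
#' Homogeneous Poisson background only; used as a null model for replay
#' statistics (chance-level recall and replay symmetry).
#'
#' @inheritParams generate_fixture
#' @param rate_hz per-neuron firing rate.
#' @return a [spike_raster()].
#' @export
poisson_raster <- function(n_neurons, duration, rate_hz, seed = NULL) {
  generate_fixture(n_neurons = n_neurons, duration = duration,
                   activation_times = numeric(0),
                   background_hz = rate_hz, seed = seed)
}
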