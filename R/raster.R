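#' Spike raster container
#'
#' A spike raster is the common currency between the simulation engine and
#' the analysis functions: a set of (neuron index, spike time) events plus
#' the number of neurons in the recorded population. Neuron indices are
#' 1-based and refer to a single linear chain (by default the cortical
#' pyramidal population).
#'
#' @param neuron integer vector of 1-based neuron indices.
#' @param time numeric vector of spike times in ms (same length as `neuron`).
#' @param n_neurons total number of neurons in the population.
#' @param t_max end of the recording window in ms (defaults to the last spike).
#' @return An object of class `spike_raster`: a data.frame with columns
#'   `neuron` and `time` (sorted by time), with attributes `n_neurons`
#'   and `t_max`.
#' @examples
#' r <- spike_raster(c(1, 2, 1), c(5, 7.5, 20), n_neurons = 10, t_max = 100)
#' print(r)
#' @export
spike_raster <- function(neuron, time, n_neurons, t_max = NULL) {
  stopifnot(length(neuron) == length(time))
  if (length(neuron)) {
    stopifnot(all(is.finite(neuron)), all(is.finite(time)))
    if (any(neuron < 1L) || any(neuron > n_neurons))
      stop("neuron indices must lie in [1, n_neurons]")
  }
  if (is.null(t_max)) t_max <- if (length(time)) max(time) else 0
  ord <- order(time, neuron)
  out <- data.frame(neuron = as.integer(neuron)[ord], time = as.numeric(time)[ord])
  attr(out, "n_neurons") <- as.integer(n_neurons)
  attr(out, "t_max") <- as.numeric(t_max)
  class(out) <- c("spike_raster", "data.frame")
  out
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster> %d spikes, %d neurons, %.1f ms\n",
              nrow(x), attr(x, "n_neurons"), attr(x, "t_max")))
  invisible(x)
}

#' @export
plot.spike_raster <- function(x, pch = ".", cex = 1.5,
                              xlim = c(0, max(attr(x, "t_max"), 1)), ...) {
  graphics::plot(if (nrow(x)) x$time else numeric(0),
                 if (nrow(x)) x$neuron else numeric(0),
                 pch = pch, cex = cex,
                 xlab = "time (ms)", ylab = "neuron", xlim = xlim,
                 ylim = c(1, attr(x, "n_neurons")), ...)
  invisible(x)
}

#' Subset a raster by time window and/or neuron set
#'
#' @param raster a [spike_raster()].
#' @param t_range numeric length-2, window `[t0, t1)` in ms, or NULL.
#' @param neurons integer vector of neuron indices to keep, or NULL.
#' @param rebase if TRUE, subtract `t_range[1]` from the spike times.
#' @return a `spike_raster` over the same population.
#' @export
raster_window <- function(raster, t_range = NULL, neurons = NULL, rebase = FALSE) {
  keep <- rep(TRUE, nrow(raster))
  if (!is.null(t_range))
    keep <- keep & raster$time >= t_range[1] & raster$time < t_range[2]
  if (!is.null(neurons))
    keep <- keep & raster$neuron %in% neurons
  out <- raster[keep, , drop = FALSE]
  tm <- attr(raster, "t_max")
  if (!is.null(t_range)) tm <- t_range[2]
  if (rebase && !is.null(t_range)) {
    out$time <- out$time - t_range[1]
    tm <- t_range[2] - t_range[1]
  }
  spike_raster(out$neuron, out$time, attr(raster, "n_neurons"), t_max = tm)
}

#' Read / write a raster as two-column TSV
#'
#' The on-disk format is a plain TSV with a `# n_neurons=<N> t_max=<T>` header
#' line followed by `neuron` and `time_ms` columns; it is the interchange
#' format between the engine, the analysis functions and stored fixtures.
#'
#' @param raster a [spike_raster()].
#' @param path file path.
#' @return `write_raster` returns `path` invisibly; `read_raster` returns a
#'   [spike_raster()].
#' @export
write_raster <- function(raster, path) {
  hdr <- sprintf("# n_neurons=%d t_max=%.6g", attr(raster, "n_neurons"),
                 attr(raster, "t_max"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, "neuron\ttime_ms"), con)
  if (nrow(raster))
    utils::write.table(data.frame(raster$neuron, sprintf("%.6g", raster$time)),
                       con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec("n_neurons=([0-9]+) t_max=([0-9.eE+-]+)", hdr))[[1]]
  if (length(m) != 3L) stop("not a raster TSV: missing header in ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  spike_raster(df[[1]], df[[2]], n_neurons = as.integer(m[2]),
               t_max = as.numeric(m[3]))
}

# Binned (neuron x time) spike-count matrix; bin in ms.
raster_matrix <- function(raster, bin = 1, t_range = NULL) {
  if (is.null(t_range)) t_range <- c(0, attr(raster, "t_max"))
  nb <- max(1L, ceiling((t_range[2] - t_range[1]) / bin))
  n <- attr(raster, "n_neurons")
  m <- matrix(0L, n, nb)
  sel <- raster$time >= t_range[1] & raster$time < t_range[2]
  if (any(sel)) {
    j <- pmin(nb, floor((raster$time[sel] - t_range[1]) / bin) + 1L)
    i <- raster$neuron[sel]
    for (k in seq_along(i)) m[i[k], j[k]] <- m[i[k], j[k]] + 1L
  }
  m
}
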