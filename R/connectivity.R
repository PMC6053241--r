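#' Default connection radii and maximal conductances
#'
#' Per-projection connection radius (in target-index units) and total
#' synaptic conductance (uS) onto one target neuron. Projections are named
#' `"SRC->TGT/RECEPTOR"`.
#'
#' @return named numeric vector.
#' @export
default_radii <- function() c(
  "PY->PY/AMPA" = 5, "PY->PY/NMDA" = 5,
  "PY->IN/AMPA" = 1, "PY->IN/NMDA" = 1,
  "IN->PY/GABAA" = 5,
  "TC->RE/AMPA" = 8, "RE->TC/GABAA" = 8, "RE->TC/GABAB" = 8,
  "RE->RE/GABAA" = 5,
  "TC->PY/AMPA" = 15, "TC->IN/AMPA" = 3,
  "PY->TC/AMPA" = 10, "PY->RE/AMPA" = 8)

#' @rdname default_radii
#' @export
default_weights <- function() c(
  "PY->PY/AMPA" = 0.24, "PY->PY/NMDA" = 0.01,
  "PY->IN/AMPA" = 0.12, "PY->IN/NMDA" = 0.01,
  "IN->PY/GABAA" = 0.24,
  "TC->RE/AMPA" = 0.06, "RE->TC/GABAA" = 0.06, "RE->TC/GABAB" = 0.0025,
  "RE->RE/GABAA" = 0.1,
  "TC->PY/AMPA" = 0.14, "TC->IN/AMPA" = 0.12,
  "PY->TC/AMPA" = 0.04, "PY->RE/AMPA" = 0.08)

# Projections carrying the miniature-PSP process, with amplitudes in mV.
default_mini_amps <- function() c(
  "PY->PY/AMPA" = 0.2, "PY->IN/AMPA" = 0.2, "IN->PY/GABAA" = 0.2)

#' Build the topographic connectivity map
#'
#' All populations are one-dimensional chains with flat (distance-
#' independent) local connectivity: target `j` receives from source `i`
#' iff `|c(i) - j| <= R`, where for equal-size populations `c(i) = i`
#' (self-connections excluded) and for different sizes `c(i)` maps the
#' source index proportionally into target coordinates
#' (`c(i) = round((i-1) * N_tgt / N_src) + 1`), preserving topography.
#' Edges are truncated at the chain boundaries. The printed conductance of
#' a projection is the total onto one target neuron and is divided equally
#' among its actual afferents, so every neuron keeps the same total
#' synaptic input regardless of boundary truncation.
#'
#' @param populations named integer vector of population sizes (defaults
#'   `c(PY = 500, IN = 100, TC = 100, RE = 100)`).
#' @param radii named radius map (see [default_radii()]); partial overrides
#'   allowed.
#' @param weights named total-conductance map (see [default_weights()]).
#' @param mini_amps named overrides of the miniature-PSP amplitudes (mV)
#'   for the mini-carrying projections.
#' @param seed accepted for interface stability; the map is deterministic.
#' @return list of class `connectivity_map`: `populations`, `radii`,
#'   `weights`, and `projections`, a named list of data.frames with
#'   columns `pre`, `post` (1-based within their populations), `weight`,
#'   `weight_init`, and for mini-carrying projections `mini_amp`,
#'   `mini_amp_init`.
#' @examples
#' cm <- build_connectivity(c(PY = 20, IN = 4, TC = 4, RE = 4))
#' nrow(cm$projections[["PY->PY/AMPA"]])
#' @export
build_connectivity <- function(populations = c(PY = 500, IN = 100,
                                               TC = 100, RE = 100),
                               radii = NULL, weights = NULL,
                               mini_amps = NULL, seed = NULL) {
  r <- default_radii(); w <- default_weights()
  if (!is.null(radii)) {
    bad <- setdiff(names(radii), names(r))
    if (length(bad)) stop("unknown projection(s): ", paste(bad, collapse = ", "))
    if (any(radii < 0)) stop("connection radius must be >= 0")
    r[names(radii)] <- radii
  }
  if (!is.null(weights)) {
    bad <- setdiff(names(weights), names(w))
    if (length(bad)) stop("unknown projection(s): ", paste(bad, collapse = ", "))
    w[names(weights)] <- weights
  }
  minis <- default_mini_amps()
  if (!is.null(mini_amps)) {
    bad <- setdiff(names(mini_amps), names(minis))
    if (length(bad)) stop("unknown mini projection(s): ",
                          paste(bad, collapse = ", "))
    minis[names(mini_amps)] <- mini_amps
  }
  projections <- list()
  for (pn in names(r)) {
    src <- sub("->.*", "", pn)
    tgt <- sub("/.*", "", sub(".*->", "", pn))
    ns <- populations[[src]]; nt <- populations[[tgt]]
    edges <- flat_edges(ns, nt, r[[pn]], same = identical(src, tgt))
    if (nrow(edges)) {
      fan_in <- tabulate(edges$post, nbins = nt)
      edges$weight <- w[[pn]] / fan_in[edges$post]
      edges$weight_init <- edges$weight
      if (pn %in% names(minis)) {
        edges$mini_amp <- minis[[pn]]
        edges$mini_amp_init <- minis[[pn]]
      }
    }
    projections[[pn]] <- edges
  }
  structure(list(populations = populations, radii = r, weights = w,
                 projections = projections),
            class = "connectivity_map")
}

flat_edges <- function(ns, nt, R, same) {
  if (R < 0) stop("connection radius must be >= 0")
  pre <- integer(0); post <- integer(0)
  centre <- if (same) seq_len(ns) else round((seq_len(ns) - 1) * nt / ns) + 1
  for (i in seq_len(ns)) {
    j <- max(1L, centre[i] - R):min(nt, centre[i] + R)
    if (same) j <- j[j != i]
    if (same && R == 0) j <- integer(0)
    pre <- c(pre, rep(i, length(j)))
    post <- c(post, j)
  }
  data.frame(pre = pre, post = post)
}

#' @export
print.connectivity_map <- function(x, ...) {
  cat("<connectivity_map>\n populations:",
      paste(sprintf("%s=%d", names(x$populations), x$populations),
            collapse = " "), "\n")
  for (pn in names(x$projections))
    cat(sprintf("  %-14s R=%2d  g=%7.4f uS  %d synapses\n", pn,
                x$radii[[pn]], x$weights[[pn]], nrow(x$projections[[pn]])))
  invisible(x)
}
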