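events_whole <- function(r) data.frame(onset = 0, offset = attr(r, "t_max"))

test_that("identical spike trains give peak correlation 1 at any distance", {
  set.seed(1)
  t_sp <- sort(runif(40, 0, 2000))
  r <- spike_raster(rep(1:20, each = 40), rep(t_sp, 20), 20, t_max = 2000)
  sc <- spatial_correlation(r, events_whole(r), distances = c(1, 5, 15),
                            n_pairs = 5)
  expect_true(all(abs(sc$mean_peak - 1) < 1e-6))
})

test_that("independent Poisson trains decorrelate with train length", {
  set.seed(2)
  peaks <- vapply(c(1000, 8000), function(dur) {
    r <- poisson_raster(30, dur, rate_hz = 10)
    sc <- spatial_correlation(r, data.frame(onset = 0, offset = dur),
                              distances = 5, n_pairs = 20,
                              normalize = "pearson")
    sc$mean_peak
  }, numeric(1))
  expect_gt(peaks[1], peaks[2])
  expect_lt(peaks[2], 0.35)
})

test_that("spatial correlation is symmetric and shift-invariant", {
  set.seed(3)
  r <- generate_fixture(n_neurons = 40, duration = 3000, start = 5,
                        background_hz = 4,
                        activation_times = seq(100, 2900, by = 400), seed = 3)
  m <- tcsleep:::raster_matrix(r, bin = 1)
  kern <- stats::dnorm(seq(-500, 500), sd = 5)
  kern <- kern / sum(kern)
  x <- tcsleep:::smooth1d(m[10, ], kern)
  y <- tcsleep:::smooth1d(m[20, ], kern)
  expect_equal(tcsleep:::xcorr_peak(x, y, 100),
               tcsleep:::xcorr_peak(y, x, 100), tolerance = 1e-10)
  expect_equal(tcsleep:::xcorr_peak(x, y, 100, "pearson"),
               tcsleep:::xcorr_peak(y, x, 100, "pearson"), tolerance = 1e-10)
  # global time shift of the whole raster leaves the estimate unchanged
  r2 <- spike_raster(r$neuron, r$time + 250, 40,
                     t_max = attr(r, "t_max") + 250)
  sc1 <- spatial_correlation(r, events_whole(r), distances = c(2, 10),
                             n_pairs = 10)
  sc2 <- spatial_correlation(r2, data.frame(onset = 250,
                                            offset = attr(r2, "t_max")),
                             distances = c(2, 10), n_pairs = 10)
  expect_equal(sc1$mean_peak, sc2$mean_peak, tolerance = 1e-6)
})

test_that("spatial correlation requires a non-empty event list", {
  r <- poisson_raster(10, 500, 5, seed = 1)
  expect_error(spatial_correlation(r, data.frame()), "empty")
})

test_that("cluster detection finds one global cluster for a traveling wave", {
  n <- 200
  times <- 100 + (1:n) * 2          # wave sweeping the whole chain
  r <- spike_raster(c(1:n, 1:n), c(times, times + 8), n, t_max = 800)
  cl <- detect_clusters(r, bin = 2, threshold = 0.2)
  big <- cl$clusters[which.max(cl$clusters$n_neurons), ]
  expect_equal(nrow(cl$clusters), 1)
  expect_gt(big$n_neurons, 0.95 * n)
})

test_that("distant bursts stay separate, nearby co-occurring ones merge", {
  n <- 200
  mk_burst <- function(lo, t0) {
    idx <- lo:(lo + 19)
    list(n = rep(idx, 3), t = rep(t0 + c(0, 5, 10), each = 20))
  }
  b1 <- mk_burst(20, 100); b2 <- mk_burst(140, 100)
  r <- spike_raster(c(b1$n, b2$n), c(b1$t, b2$t), n, t_max = 300)
  cl <- detect_clusters(r, threshold = 0.3)
  expect_equal(nrow(cl$clusters), 2)
  expect_equal(nrow(cl$merged), 2)     # 100 neurons apart: no merge

  b3 <- mk_burst(20, 100); b4 <- mk_burst(43, 100)  # 3-neuron gap
  r2 <- spike_raster(c(b3$n, b4$n), c(b3$t, b4$t), n, t_max = 300)
  cl2 <- detect_clusters(r2, threshold = 0.3, merge_dist = 5)
  if (nrow(cl2$clusters) >= 2) expect_lt(nrow(cl2$merged), nrow(cl2$clusters))
  else expect_equal(nrow(cl2$merged), 1)
})

test_that("cluster labels partition the suprathreshold pixels", {
  set.seed(4)
  r <- generate_fixture(n_neurons = 80, duration = 1000, start = 10,
                        background_hz = 10, activation_times = c(200, 600),
                        seed = 4)
  cl <- detect_clusters(r)
  lab <- cl$labels
  expect_true(all(lab >= 0))
  # every labelled pixel belongs to exactly one cluster and the cluster
  # pixel counts sum to the labelled area
  expect_equal(sum(cl$clusters$n_pixels), sum(lab > 0))
})

test_that("empty segments produce no clusters", {
  r <- spike_raster(integer(0), numeric(0), 50, t_max = 400)
  cl <- detect_clusters(r)
  expect_equal(nrow(cl$clusters), 0)
})
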