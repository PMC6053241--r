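test_that("weight trajectories report relative change over a mask", {
  times <- seq(0, 4000, by = 1000)
  w <- matrix(0.02, length(times), 6)
  tr <- weight_trajectory(times, w, mask = 1:3)
  expect_true(all(tr$mean_rel_change == 0))

  w2 <- w
  w2[, 1:3] <- w2[, 1:3] * seq(1, 1.8, length.out = length(times))
  tr2 <- weight_trajectory(times, w2, mask = 1:3)
  expect_equal(tr2$mean_rel_change[length(times)], 0.8, tolerance = 1e-10)
  expect_error(weight_trajectory(times, w, mask = rep(FALSE, 6)), "empty")
})

test_that("consolidation probability counts positive final trends", {
  flat <- data.frame(time = seq(0, 2e5, by = 1e4),
                     mean_rel_change = rep(0.1, 21))
  up <- transform(flat, mean_rel_change = seq(0, 0.5, length.out = 21))
  down <- transform(flat, mean_rel_change = seq(0.5, 0, length.out = 21))
  out <- consolidation_probability(list(up, up, down, flat))
  expect_equal(out$probability, 0.5)
  expect_error(consolidation_probability(list(flat[1, ])), "fewer than 2")
})

test_that("planted noisy trends are recovered at the planted proportion", {
  set.seed(9)
  p_true <- 0.7
  n_rep <- 100
  trs <- lapply(seq_len(n_rep), function(i) {
    slope <- if (i <= p_true * n_rep) 1e-6 else -1e-6
    t <- seq(0, 2e5, by = 5e3)
    data.frame(time = t,
               mean_rel_change = slope * t + rnorm(length(t), sd = 0.02))
  })
  out <- consolidation_probability(trs)
  expect_lt(abs(out$probability - p_true),
            3 * sqrt(p_true * (1 - p_true) / n_rep) + 0.05)
})

test_that("the sequence mask selects forward synapses inside the span", {
  cm <- build_connectivity(c(PY = 50, IN = 10, TC = 10, RE = 10))
  chain <- 20:30
  mfwd <- sequence_weight_mask(cm, chain)
  mbwd <- sequence_weight_mask(cm, chain, backward = TRUE)
  syn <- cm$projections[["PY->PY/AMPA"]]
  expect_true(all(syn$pre[mfwd] %in% chain & syn$post[mfwd] %in% chain))
  expect_true(all(syn$post[mfwd] > syn$pre[mfwd]))
  expect_true(all(syn$post[mbwd] < syn$pre[mbwd]))
  expect_false(any(mfwd & mbwd))
  # a descending chain flips the orientation
  mdesc <- sequence_weight_mask(cm, rev(chain))
  expect_true(all(syn$post[mdesc] < syn$pre[mdesc]))
})

test_that("untrained-location scan reports per-location differences", {
  set.seed(10)
  before <- poisson_raster(200, 5000, rate_hz = 6)
  after <- poisson_raster(200, 5000, rate_hz = 6)
  onsets <- seq(100, 4100, by = 1000)
  out <- untrained_location_scan(before, after, onsets, onsets,
                                 locations = c(30, 60), directions = c(1, -1),
                                 trained_span = 100:124)
  expect_equal(nrow(out), 4)
  expect_true(all(!out$overlaps_trained))
  expect_true(all(abs(out$diff) <= 100))
  # direction reversal at one location yields two independent rows
  expect_equal(sum(out$location == 30), 2)
  # overlap with the trained span is flagged
  out2 <- untrained_location_scan(before, after, onsets, onsets,
                                  locations = 110, directions = 1,
                                  trained_span = 100:124)
  expect_true(out2$overlaps_trained)
})
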