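test_that("string match reproduces the worked scoring examples", {
  expect_equal(string_match("ACDB", "ABCDE"), 0.4)
  expect_equal(string_match("ACDB", "ABCDE", normalize = FALSE), 4)
  expect_equal(string_match("ABCDE", "ABCDE"), 1.0)
  expect_equal(string_match("EDCBA", "ABCDE"), -0.2)
  expect_equal(string_match("", "ABCDE"), 0)
  expect_equal(string_match(character(0), "ABCDE"), 0)
  expect_error(string_match("ABC", ""), "non-empty")
})

test_that("string match handles duplicates and foreign labels", {
  # duplicates collapse to the first occurrence before scoring
  expect_equal(string_match("AABC", "ABCDE"), string_match("ABC", "ABCDE"))
  # labels outside the ideal alphabet are dropped
  expect_equal(string_match("AXBZC", "ABCDE"), string_match("ABC", "ABCDE"))
})

test_that("string match agrees with a brute-force scorer on random pairs", {
  set.seed(42)
  for (i in 1:2000) {
    p <- random_sequence_pair()
    expect_equal(string_match(p$s1, p$s), sm_bruteforce(p$s1, p$s),
                 info = paste(p$s1, "vs", p$s))
  }
})

test_that("recall-sequence detection orders groups by smoothed peak time", {
  r <- generate_fixture(n_neurons = 300, duration = 400, start = 100,
                        lag_ms = 15, seed = 1)
  groups <- attr(r, "groups")
  expect_equal(detect_recall_sequence(r, groups), LETTERS[1:5])

  rev_r <- generate_fixture(n_neurons = 300, duration = 400, start = 100,
                            sequence = LETTERS[5:1], lag_ms = 15, seed = 1)
  expect_equal(detect_recall_sequence(rev_r, attr(rev_r, "groups")),
               LETTERS[5:1])
})

test_that("silent groups are omitted from the detected sequence", {
  r <- generate_fixture(n_neurons = 300, duration = 400, start = 100,
                        lag_ms = 15, seed = 1)
  groups <- attr(r, "groups")
  keep <- !(r$neuron %in% groups$C)
  r2 <- spike_raster(r$neuron[keep], r$time[keep], 300, t_max = 400)
  det <- detect_recall_sequence(r2, groups)
  expect_equal(det, c("A", "B", "D", "E"))
  expect_length(det, 4)
})

test_that("recall performance is the percentage above threshold", {
  expect_equal(recall_performance(rep(1, 10)), 100)
  expect_equal(recall_performance(c(1.0, 0.4, 0.9), th = 0.8), 200 / 3)
  expect_error(recall_performance(numeric(0)), "no trials")
  expect_error(recall_performance(c(1), th = 0))
})

test_that("noise-only recall matches the permutation chance oracle", {
  # with dense background every group fires, so the detected order is a
  # random permutation; P(SM >= 0.8) by enumeration over all 120 orders
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 5), ]
  chance <- mean(apply(perms, 1, function(p)
    string_match(LETTERS[p], LETTERS[1:5]) >= 0.8))
  set.seed(7)
  scores <- replicate(400, {
    r <- poisson_raster(60, 350, rate_hz = 12)
    groups <- split(26:50, rep(1:5, each = 5))
    names(groups) <- LETTERS[1:5]
    string_match(detect_recall_sequence(r, groups), LETTERS[1:5])
  })
  perf <- recall_performance(scores, th = 0.8) / 100
  se <- sqrt(chance * (1 - chance) / 400)
  expect_lt(abs(perf - chance), 4 * se + 0.01)
})

test_that("replay detection recovers a planted chain and degrades with jitter", {
  r <- generate_fixture(n_neurons = 100, duration = 500, start = 30,
                        lag_ms = 5, activation_times = c(50, 250), seed = 2)
  rep0 <- detect_replays(r, neurons = 30:54)
  expect_equal(rep0$n_candidates, 2)
  expect_equal(rep0$correct, 2)
  expect_equal(rep0$reverse, 0)
  expect_true(all(rep0$scores$sm_forward == 1))

  # moderate jitter keeps the order, large jitter destroys it
  sm_at_jitter <- vapply(c(2, 8, 40), function(j) {
    set.seed(5)
    rj <- generate_fixture(n_neurons = 100, duration = 500, start = 30,
                           lag_ms = 5, jitter_sd = j,
                           activation_times = c(50, 250), seed = j)
    mean(detect_replays(rj, neurons = 30:54)$scores$sm_forward)
  }, numeric(1))
  expect_true(sm_at_jitter[1] >= sm_at_jitter[3])
  expect_gt(sm_at_jitter[1], 0.9)
})

test_that("chain links beyond the gap threshold are rejected, anchor carried", {
  # neuron 2 spikes far away; chain must still complete via the anchor
  neurons <- 1:10
  times <- c(100, 300, seq(106, 120, by = 2))   # neuron 2 at 300 ms
  nrn <- c(1, 2, 3:10)
  r <- spike_raster(nrn, times, 20, t_max = 500)
  out <- detect_replays(r, neurons = 1:10, group_size = 5, max_gap = 50)
  expect_equal(out$n_candidates, 1)
  # group B (neurons 6-10) average uses only accepted spikes
  expect_equal(out$correct, 1)
})

test_that("replay direction is symmetric on homogeneous Poisson rasters", {
  set.seed(11)
  fwd <- rev <- 0
  for (k in 1:20) {
    r <- poisson_raster(60, 4000, rate_hz = 8)
    out <- detect_replays(r, neurons = 11:35, th = 0.8)
    fwd <- fwd + out$correct
    rev <- rev + out$reverse
  }
  # two-sided binomial check: neither direction dominates
  n <- fwd + rev
  if (n > 0) {
    p <- stats::binom.test(fwd, n, 0.5)$p.value
    expect_gt(p, 0.001)
  }
  expect_true(TRUE)
})

test_that("session scoring ties trials to their stimulus onsets", {
  r <- generate_fixture(n_neurons = 200, duration = 3000, start = 100,
                        lag_ms = 15, activation_times = c(210, 1210, 2210),
                        seed = 3)
  groups <- attr(r, "groups")
  sc <- score_session(r, groups, onsets = c(200, 1200, 2200))
  expect_equal(nrow(sc), 3)
  expect_true(all(sc$sm == 1))
})
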