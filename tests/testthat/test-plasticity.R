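test_that("the STDP window has the stated amplitudes and symmetry", {
  p <- stage_plasticity("awake")
  expect_equal(stdp_F(1e-9, p), 0.002, tolerance = 1e-6)
  expect_equal(stdp_F(20, p), 0.002 * exp(-1))
  expect_equal(stdp_F(20, p), 7.358e-4, tolerance = 1e-4)
  dts <- c(0.5, 2, 7, 20, 55)
  expect_equal(stdp_F(-dts, p), -stdp_F(dts, p))
  expect_equal(stdp_F(0, p), 0)
  expect_true(all(abs(stdp_F(seq(-100, 100, by = 0.5), p)) <= p$A_plus))
})

test_that("stage plasticity halves the amplitude in N3 only", {
  expect_equal(stage_plasticity("awake")$A_plus, 0.002)
  expect_equal(stage_plasticity("n2")$A_plus, 0.002)
  expect_equal(stage_plasticity("n3")$A_plus, 0.001)
  expect_equal(stage_plasticity("n3")$A_minus, 0.001)
  # stateless: switching back restores the awake value
  stage_plasticity("n3")
  expect_equal(stage_plasticity("awake")$A_plus, 0.002)
  expect_error(stage_plasticity("rem"))
})

test_that("one pairing updates the weight by g_max * F and clips at bounds", {
  w0 <- 0.024
  up <- apply_stdp(w0, w0, dt = 10, g_max = 0.24)
  expect_equal(up$weight, w0 + 0.24 * 0.002 * exp(-0.5))
  # at the 200% cap a potentiating pair leaves the weight unchanged
  atcap <- apply_stdp(2 * w0, w0, dt = 5, g_max = 0.24)
  expect_equal(atcap$weight, 2 * w0)
  # depression floors at zero
  floor <- apply_stdp(1e-6, w0, dt = -1, g_max = 0.24)
  expect_equal(floor$weight, 0)
  # mini amplitude co-plasticity uses the slow factor f
  both <- apply_stdp(w0, w0, dt = 10, g_max = 0.24,
                     mini_amp = 0.2, mini_amp_init = 0.2)
  expect_equal(both$mini_amp, 0.2 + 0.01 * 0.2 * 0.002 * exp(-0.5))
})

test_that("repeated forward pairing drives the weight to the cap", {
  w0 <- w <- 0.024
  for (i in 1:500) w <- apply_stdp(w, w0, dt = 5, g_max = 0.24)$weight
  expect_equal(w, 2 * w0)
  # and never leaves [0, 200%] on the way
  w <- w0
  path <- replicate(200, w <<- apply_stdp(w, w0, dt = 5, g_max = 0.24)$weight)
  expect_true(all(path >= 0 & path <= 2 * w0 + 1e-12))
})

test_that("offline training on an ordered raster skews forward weights", {
  cm <- build_connectivity(c(PY = 60, IN = 12, TC = 12, RE = 12))
  # groups fire in order, 5 ms apart, 50 trials
  r <- generate_fixture(n_neurons = 60, duration = 50 * 200, start = 18,
                        lag_ms = 5,
                        activation_times = seq(10, 50 * 200 - 100, by = 200),
                        seed = 1)
  trained <- train_stdp(cm, r)
  syn0 <- cm$projections[["PY->PY/AMPA"]]
  syn1 <- trained$projections[["PY->PY/AMPA"]]
  chain <- 18:42
  fwd <- sequence_weight_mask(cm, chain)
  bwd <- sequence_weight_mask(cm, chain, backward = TRUE)
  dfwd <- syn1$weight[fwd] - syn0$weight[fwd]
  dbwd <- syn1$weight[bwd] - syn0$weight[bwd]
  expect_gt(mean(dfwd), 0)
  expect_lt(mean(dbwd), 0)
  expect_true(all(syn1$weight >= 0 & syn1$weight <= 2 * syn1$weight_init))
})

test_that("symmetric random firing produces no systematic drift", {
  set.seed(21)
  cm <- build_connectivity(c(PY = 30, IN = 6, TC = 6, RE = 6))
  r <- poisson_raster(30, 12000, rate_hz = 5)
  trained <- train_stdp(cm, r)
  syn0 <- cm$projections[["PY->PY/AMPA"]]$weight
  syn1 <- trained$projections[["PY->PY/AMPA"]]$weight
  drift <- mean((syn1 - syn0) / syn0)
  # expected drift 0 under the symmetric window; allow Monte-Carlo error
  expect_lt(abs(drift), 0.05)
})
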