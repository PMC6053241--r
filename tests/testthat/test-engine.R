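test_that("a zero-duration schedule returns an empty record", {
  net <- small_net()
  rec <- simulate_network(net, data.frame(stage = character(0),
                                          duration = numeric(0)))
  expect_s3_class(rec, "tc_record")
  expect_equal(nrow(rec$spikes), 0)
  expect_equal(attr(rec$raster, "t_max"), 0)
})

test_that("identical configuration and seed reproduce the raster exactly", {
  net <- small_net()
  sched <- data.frame(stage = "n2", duration = 1500)
  a <- simulate_network(net, sched, seed = 7, snapshot_ms = 0)
  b <- simulate_network(net, sched, seed = 7, snapshot_ms = 0)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$lfp, b$lfp)
  c <- simulate_network(net, sched, seed = 8, snapshot_ms = 0)
  expect_false(identical(a$spikes, c$spikes))
})

test_that("training trials activate groups at 15 ms onset spacing", {
  pr <- stim_protocol(start = 10, amplitude = 5)
  ev <- stim_events(pr, "train", t_start = 0, n_trials = 2)
  on_a <- sort(unique(ev$t_on[ev$neuron %in% pr$groups$A]))
  on_e <- sort(unique(ev$t_on[ev$neuron %in% pr$groups$E]))
  expect_equal(on_a, c(0, 1000))
  expect_equal(on_e, c(60, 1060))
  expect_equal(sort(unique(ev$t_on[ev$t_on < 1000])), c(0, 15, 30, 45, 60))
  expect_true(all(ev$t_off - ev$t_on == 10))
})

test_that("test trials stimulate only the first group of the order", {
  pr <- stim_protocol(start = 10)
  ev <- stim_events(pr, "test", t_start = 500, n_trials = 3)
  expect_true(all(ev$neuron %in% pr$groups$A))
  expect_equal(attr(ev, "onsets"), c(500, 1500, 2500))
})

test_that("non-linear protocols activate groups in the stated order", {
  pr <- stim_protocol(start = 200, group_size = 2,
                      order = c("A", "C", "B", "D", "E"))
  expect_equal(pr$groups$A, c(200, 201))
  expect_equal(pr$groups$C, c(204, 205))
  ev <- stim_events(pr, "train", t_start = 0, n_trials = 1)
  first_by_group <- vapply(split(ev$t_on, findInterval(ev$neuron,
    c(200, 202, 204, 206, 208))), min, numeric(1))
  # activation times follow A(200-201), C(204-205), B(202-203), D, E
  expect_equal(unname(first_by_group), c(0, 30, 15, 45, 60))
})

test_that("sessions and groups outside the run are rejected", {
  net <- small_net()
  pr <- stim_protocol(start = 10, group_size = 2)
  expect_error(simulate_network(net, data.frame(stage = "awake",
                                                duration = 1000),
    sessions = list(list(protocol = pr, mode = "test", t_start = 900,
                         n_trials = 2)), seed = 1), "outside the schedule")
  pr_bad <- stim_protocol(start = 55, group_size = 5)  # beyond 60 PY
  expect_error(simulate_network(net, data.frame(stage = "awake",
                                                duration = 2000),
    sessions = list(list(protocol = pr_bad, mode = "train", t_start = 100,
                         n_trials = 1)), seed = 1), "outside the network")
})

test_that("RK4 integration shows fourth-order error scaling", {
  # leak-only cell against the closed-form exponential over one decade of dt
  p <- cell_params("PY", g_Na_dend = 0, g_Nap_dend = 0, g_Km = 0,
                   g_KCa = 0, g_HVA = 0, G_KL = 0, kappa_Mohm = 1e12,
                   g_Na_soma = 0, g_K_soma = 0, g_Nap_soma = 0,
                   G_L = 0.3)                 # fast decay: visible error
  tau <- p$C_m / p$G_L
  errs <- vapply(c(0.4, 0.2, 0.1, 0.05), function(dt) {
    out <- single_cell(p, "awake", duration = 10, dt = dt, v0 = p$E_L + 20,
                       record_every = 1)
    vt <- out$v[length(out$v)]
    t_end <- out$t[length(out$t)]
    abs(vt - (p$E_L + 20 * exp(-t_end / tau)))
  }, numeric(1))
  orders <- log2(errs[-length(errs)] / errs[-1])
  expect_true(all(orders > 3.3))
})

test_that("stimulated pyramidal groups spike within the pulse window", {
  net <- small_net()
  pr <- stim_protocol(start = 20, amplitude = 8)
  rec <- simulate_network(net, data.frame(stage = "awake", duration = 2000),
    sessions = list(list(protocol = pr, mode = "test", t_start = 500,
                         n_trials = 1)),
    seed = 3, snapshot_ms = 0)
  resp <- rec$raster[rec$raster$time >= 500 & rec$raster$time < 540, ]
  expect_gt(sum(resp$neuron %in% pr$groups$A), 0)
})

test_that("weight snapshots are monotone in time and bounded", {
  net <- small_net()
  pr <- stim_protocol(start = 20, amplitude = 8)
  rec <- simulate_network(net, data.frame(stage = "awake", duration = 3000),
    sessions = list(list(protocol = pr, mode = "train", t_start = 200,
                         n_trials = 2)),
    seed = 3, snapshot_ms = 1000)
  expect_true(all(diff(rec$weight_times) > 0))
  w0 <- net$connectivity$projections[["PY->PY/AMPA"]]$weight_init
  expect_true(all(rec$weights >= 0))
  expect_true(all(t(rec$weights) <= 2 * w0 + 1e-12))
})

test_that("raster round-trips through the TSV interchange format", {
  r <- generate_fixture(n_neurons = 80, duration = 500, start = 10,
                        background_hz = 3, seed = 6)
  path <- tempfile(fileext = ".tsv")
  write_raster(r, path)
  r2 <- read_raster(path)
  expect_equal(attr(r2, "n_neurons"), 80)
  expect_equal(attr(r2, "t_max"), 500)
  expect_equal(r2$neuron, r$neuron)
  expect_equal(r2$time, r$time, tolerance = 1e-5)
  unlink(path)
})

test_that("records persist and reload through the plain-text container", {
  net <- small_net()
  rec <- simulate_network(net, data.frame(stage = "awake", duration = 800),
                          seed = 2, snapshot_ms = 400)
  dir <- tempfile()
  save_record(rec, dir)
  back <- load_record(dir)
  expect_equal(nrow(back$raster), nrow(rec$raster))
  expect_equal(back$lfp, rec$lfp, tolerance = 1e-6)
  expect_equal(back$lfp_fs, rec$lfp_fs)
  unlink(dir, recursive = TRUE)
})
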