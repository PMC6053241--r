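test_that("synaptic currents vanish with closed channels or at reversal", {
  for (rec in c("AMPA", "NMDA", "GABAA", "GABAB"))
    expect_equal(synaptic_current(rec, 0, -65, 0.24), 0)
  expect_equal(synaptic_current("AMPA", 1, 0, 0.24, "PY->PY/AMPA", "awake"), 0)
  expect_equal(synaptic_current("GABAA", 0.5, -70, 0.24), 0)
})

test_that("stage switching scales currents by the printed factor ratios", {
  i_awake <- synaptic_current("AMPA", 0.4, -60, 0.24, "PY->PY/AMPA", "awake")
  i_n3 <- synaptic_current("AMPA", 0.4, -60, 0.24, "PY->PY/AMPA", "n3")
  expect_equal(i_n3 / i_awake, 0.4332 / 0.133)
  i_n2 <- synaptic_current("GABAA", 0.2, -60, 0.24, "IN->PY/GABAA", "n2")
  i_aw <- synaptic_current("GABAA", 0.2, -60, 0.24, "IN->PY/GABAA", "awake")
  expect_equal(i_n2 / i_aw, 0.264 / 0.22)
  # NMDA and corticothalamic AMPA are not stage-scaled
  expect_equal(stage_synaptic_factor("PY->PY/NMDA", "n3"), 1)
  expect_equal(stage_synaptic_factor("PY->TC/AMPA", "n3"), 1)
  expect_equal(stage_synaptic_factor("RE->TC/GABAB", "n3"), 1)
})

test_that("stage parameter tables carry the printed neuromodulator levels", {
  aw <- stage_params("awake"); n2 <- stage_params("n2"); n3 <- stage_params("n3")
  expect_equal(unname(aw$ach_gkl[c("PY", "TC", "RE")]), c(0.133, 0.4, 0.9))
  expect_equal(unname(n2$ach_gkl[c("PY", "TC", "RE")]), c(0.228, 0.96, 0.81))
  expect_equal(unname(n3$ach_gkl[c("PY", "TC", "RE")]), c(0.38, 1.6, 0.45))
  expect_equal(unname(c(aw$ach_ampa["PY"], n2$ach_ampa["PY"],
                        n3$ach_ampa["PY"])), c(0.133, 0.1938, 0.4332))
  expect_equal(unname(c(aw$gaba_gabaa["IN"], n2$gaba_gabaa["IN"],
                        n3$gaba_gabaa["IN"])), c(0.22, 0.264, 0.44))
  expect_equal(c(aw$ha_gh, n2$ha_gh, n3$ha_gh), c(-24, -2, -1))
  expect_true(all(unlist(lapply(list(aw, n2, n3), function(s)
    c(s$ach_gkl, s$ach_ampa, s$gaba_gabaa))) > 0))
})

test_that("first-order receptor kinetics rest at zero and bound at one", {
  none <- synapse_response("AMPA", numeric(0), duration = 200)
  expect_true(all(none$value == 0))
  one <- synapse_response("AMPA", 50, duration = 400)
  expect_gt(max(one$value), 0)
  expect_lte(max(one$value), 1)
  # rises then decays
  pk <- which.max(one$value)
  expect_lt(one$t[pk], 60)
  expect_lt(one$value[length(one$value)], max(one$value) / 2)
})

test_that("the G-protein cascade responds superlinearly to bursts", {
  single <- synapse_response("GABAB", 100, duration = 1500)
  burst <- synapse_response("GABAB", c(100, 110, 120, 130), duration = 1500)
  expect_gt(max(burst$value), max(single$value))
  # a single spike barely engages GABA-B compared with GABA-A
  ga <- synapse_response("GABAA", 100, duration = 1500)
  expect_lt(max(single$value), 0.1 * max(ga$value))
})

test_that("the mini intensity integrates to the empirical event rate", {
  # thinning sampler driven by the package rate function, 10 seeds
  t0 <- 0; T_end <- 2000
  mu_int <- stats::integrate(function(t) mini_rate(t, t0), t0, T_end)$value
  counts <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 0; t <- t0
    repeat {
      t <- t + stats::rexp(1, 1 / 250)    # envelope at the asymptote
      if (t > T_end) break
      if (runif(1) < mini_rate(t, t0) / (1 / 250)) n <- n + 1
    }
    n
  }, numeric(1))
  expect_lt(abs(mean(counts) - mu_int) / mu_int,
            4 / sqrt(sum(counts)) + 0.05)
})
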