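test_that("all documented presets build valid experiment designs", {
  names <- c("fig2_single_seq", "fig3_no_sleep", "fig3_n2_only",
             "fig3_n3_only", "fig5_two_seq_n3", "fig6_seq2_duration_sweep",
             "fig7_two_seq_n2n3", "fig8_n2_duration_sweep",
             "s3_nonlinear_acbde", "s4_awake_rate", "s5_spindle_density",
             "s6_so_frequency", "s7_distance_orientation_sweep")
  for (nm in names) {
    p <- experiment_preset(nm, scale = 0.05)
    d <- build_experiment(p)
    expect_true(all(d$schedule$duration > 0), info = nm)
    # sessions lie inside the schedule
    t_total <- sum(d$schedule$duration)
    for (ss in d$sessions) {
      expect_gte(ss$t_start, 0)
      expect_lte(ss$t_start + ss$n_trials * 1000, t_total)
    }
    expect_true(all(c("baseline", "after_training", "after_sleep") %in%
                      names(d$markers)), info = nm)
  }
})

test_that("two-sequence presets place the sequences as documented", {
  p <- experiment_preset("fig5_two_seq_n3")
  d <- build_experiment(p)
  expect_equal(d$protocol1$groups$A, 200:204)
  expect_equal(d$protocol1$groups$E, 220:224)
  # Seq2 descends from #300
  expect_equal(d$protocol2$groups$A, 300:296)
  expect_equal(p$sleep_stages, "n3")
  p7 <- experiment_preset("fig7_two_seq_n2n3")
  expect_equal(p7$sleep_stages, c("n2", "n3"))
})

test_that("the non-linear preset uses two-cell groups in ACBDE order", {
  p <- experiment_preset("s3_nonlinear_acbde")
  d <- build_experiment(p)
  expect_equal(p$group_size, 2L)
  expect_equal(p$order, c("A", "C", "B", "D", "E"))
  expect_equal(d$protocol1$groups$A, 200:201)
  expect_equal(d$protocol1$groups$E, 208:209)
})

test_that("scale shrinks stage durations and trial counts together", {
  p1 <- experiment_preset("fig3_n3_only", scale = 1)
  p2 <- experiment_preset("fig3_n3_only", scale = 0.1)
  expect_equal(p1$sleep_ms, 5e5)
  expect_equal(p2$sleep_ms, 5e4)
  expect_equal(p1$train_trials, 100L)
  expect_equal(p2$train_trials, 10L)
  expect_equal(p1$test_trials, 50L)
  d <- build_experiment(p1)
  expect_equal(d$schedule$stage, c("awake", "n3", "awake"))
})

test_that("an empty sweep grid is rejected; the sweep table is tidy", {
  p <- experiment_preset("fig6_seq2_duration_sweep", scale = 0.05,
                         populations = small_pops)
  expect_error(sweep_preset(p, data.frame()), "empty")
})

test_that("a tiny preset run produces the full result bundle", {
  p <- experiment_preset("fig3_no_sleep", scale = 0.02,
                         populations = small_pops, test_trials = 150,
                         train_s = 150, sleep_s = 150)
  res <- run_preset(p, seeds = 1, snapshot_ms = 2000)
  expect_s3_class(res, "experiment_result")
  expect_false(res$manifest$partial)
  expect_equal(sort(unique(res$per_seed$marker)),
               sort(c("baseline", "after_training", "after_sleep")))
  expect_true(all(res$per_seed$performance >= 0 &
                    res$per_seed$performance <= 100))
  expect_true(!is.null(res$replays))
  expect_equal(nrow(res$summary), 3)
})
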