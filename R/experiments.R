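#' Experiment presets
#'
#' Named experiment designs combining a stage schedule, training/test
#' protocols and parameter overrides. Every preset carries a `scale` knob
#' (1 = full design durations; smaller values shrink stage durations and
#' trial counts together for smoke-scale runs) and follows the canonical
#' session layout: awake (test, train, test), sleep stage(s), awake
#' (test).
#'
#' Available presets:
#' * `fig2_single_seq` - single sequence, N2 then N3 sleep.
#' * `fig3_no_sleep` - training followed by an equivalent awake period.
#' * `fig3_n2_only`, `fig3_n3_only` - one sleep stage only.
#' * `fig5_two_seq_n3` - strong Seq1 (100 s at #200, ascending) and weak
#'   Seq2 (40 s at #300, descending), N3 sleep only.
#' * `fig6_seq2_duration_sweep` - as `fig5_two_seq_n3`; sweep template
#'   over the Seq2 training duration.
#' * `fig7_two_seq_n2n3` - both sequences, 500 s N2 before N3.
#' * `fig8_n2_duration_sweep` - sweep template over the N2 duration.
#' * `s3_nonlinear_acbde` - non-linear order A-C-B-D-E with group size 2.
#' * `s4_awake_rate` - awake-only, optional raised mini amplitude.
#' * `s5_spindle_density` - N2 only, optional reduced relay potassium
#'   leak.
#' * `s6_so_frequency` - N3 only, optional reduced AMPA strength.
#' * `s7_distance_orientation_sweep` - sweep template over Seq2 location
#'   and direction.
#'
#' @param name preset name.
#' @param scale duration/trial scaling in (0, 1].
#' @param populations population sizes for the runs.
#' @param test_trials test-session trials at scale 1 (default 50).
#' @param train_s Seq1 training duration (s) at scale 1.
#' @param train2_s Seq2 training duration (s) at scale 1 (two-sequence
#'   presets).
#' @param sleep_s per-stage sleep duration (s) at scale 1.
#' @param seq2_start,seq2_direction Seq2 geometry (defaults #300,
#'   descending).
#' @param stim_amplitude stimulation current density (uA/cm2).
#' @return list of class `experiment_preset`.
#' @export
experiment_preset <- function(name = c("fig2_single_seq", "fig3_no_sleep",
                                       "fig3_n2_only", "fig3_n3_only",
                                       "fig5_two_seq_n3",
                                       "fig6_seq2_duration_sweep",
                                       "fig7_two_seq_n2n3",
                                       "fig8_n2_duration_sweep",
                                       "s3_nonlinear_acbde", "s4_awake_rate",
                                       "s5_spindle_density",
                                       "s6_so_frequency",
                                       "s7_distance_orientation_sweep"),
                              scale = 1,
                              populations = c(PY = 500, IN = 100,
                                              TC = 100, RE = 100),
                              test_trials = 50, train_s = 100,
                              train2_s = 40, sleep_s = 500,
                              seq2_start = 300, seq2_direction = -1,
                              stim_amplitude = 8) {
  name <- match.arg(name)
  stopifnot(scale > 0, scale <= 1)
  p <- list(name = name, scale = scale, populations = populations,
            test_trials = max(5L, as.integer(round(test_trials * scale))),
            train_trials = max(5L, as.integer(round(train_s * scale))),
            train2_trials = max(2L, as.integer(round(train2_s * scale))),
            sleep_ms = 1000 * sleep_s * scale,
            seq2_start = seq2_start, seq2_direction = seq2_direction,
            stim_amplitude = stim_amplitude,
            group_size = if (name == "s3_nonlinear_acbde") 2L else 5L,
            order = if (name == "s3_nonlinear_acbde")
              c("A", "C", "B", "D", "E") else LETTERS[1:5],
            two_seq = name %in% c("fig5_two_seq_n3",
                                  "fig6_seq2_duration_sweep",
                                  "fig7_two_seq_n2n3",
                                  "fig8_n2_duration_sweep",
                                  "s7_distance_orientation_sweep"),
            sleep_stages = switch(name,
              fig2_single_seq = c("n2", "n3"),
              fig3_no_sleep = "awake",
              fig3_n2_only = "n2",
              fig3_n3_only = "n3",
              fig5_two_seq_n3 = "n3",
              fig6_seq2_duration_sweep = "n3",
              fig7_two_seq_n2n3 = c("n2", "n3"),
              fig8_n2_duration_sweep = c("n2", "n3"),
              s3_nonlinear_acbde = c("n2", "n3"),
              s4_awake_rate = "awake",
              s5_spindle_density = "n2",
              s6_so_frequency = "n3"),
            net_args = list())
  # paper-style scale of the trained span relative to the network
  scale_idx <- function(i) as.integer(round(i * populations[["PY"]] / 500))
  p$seq1_start <- scale_idx(200)
  p$seq2_start <- scale_idx(seq2_start)
  class(p) <- "experiment_preset"
  p
}

#' Build the schedule and sessions of a preset
#'
#' Expands a preset into the `schedule` and `sessions` arguments of
#' [simulate_network()], plus session markers used by the analysis.
#'
#' @param preset an [experiment_preset()].
#' @return list with `schedule`, `sessions`, `markers` (named list of
#'   session indices: `baseline`, `after_training`, `after_sleep`),
#'   `protocol1`, `protocol2` (NULL for single-sequence presets) and
#'   `sleep_window` (ms range of the sleep block).
#' @export
build_experiment <- function(preset) {
  p <- preset
  pr1 <- stim_protocol(start = p$seq1_start, group_size = p$group_size,
                       order = p$order, amplitude = p$stim_amplitude)
  pr2 <- if (p$two_seq)
    stim_protocol(start = p$seq2_start, direction = p$seq2_direction,
                  amplitude = p$stim_amplitude) else NULL
  ms <- function(trials) trials * 1000
  sessions <- list(); markers <- list(); t <- 0
  add <- function(proto, mode, n) {
    sessions[[length(sessions) + 1L]] <<-
      list(protocol = proto, mode = mode, t_start = t, n_trials = n)
    length(sessions)
  }
  # baseline tests
  markers$baseline <- add(pr1, "test", p$test_trials)
  t <- t + ms(p$test_trials)
  if (p$two_seq) {
    markers$baseline2 <- add(pr2, "test", p$test_trials)
    t <- t + ms(p$test_trials)
  }
  # training
  add(pr1, "train", p$train_trials)
  t <- t + ms(p$train_trials)
  if (p$two_seq) {
    add(pr2, "train", p$train2_trials)
    t <- t + ms(p$train2_trials)
  }
  # post-training tests
  markers$after_training <- add(pr1, "test", p$test_trials)
  t <- t + ms(p$test_trials)
  if (p$two_seq) {
    markers$after_training2 <- add(pr2, "test", p$test_trials)
    t <- t + ms(p$test_trials)
  }
  awake1 <- t
  sleep_start <- t
  stages <- data.frame(stage = "awake", duration = awake1)
  for (st in p$sleep_stages) {
    stages <- rbind(stages, data.frame(stage = st, duration = p$sleep_ms))
    t <- t + p$sleep_ms
  }
  sleep_end <- t
  # post-sleep tests in a final awake block
  markers$after_sleep <- add(pr1, "test", p$test_trials)
  t <- t + ms(p$test_trials)
  if (p$two_seq) {
    markers$after_sleep2 <- add(pr2, "test", p$test_trials)
    t <- t + ms(p$test_trials)
  }
  stages <- rbind(stages, data.frame(stage = "awake", duration = t - sleep_end))
  list(schedule = stages, sessions = sessions, markers = markers,
       protocol1 = pr1, protocol2 = pr2,
       sleep_window = c(sleep_start, sleep_end))
}

#' Run an experiment preset over replicate seeds
#'
#' Executes simulate-then-analyze for each seed: builds the network (with
#' the preset's parameter overrides), runs the schedule, scores every test
#' session, counts replays inside the sleep block and extracts the
#' sequence weight trajectory. Aggregates performance as mean and SEM
#' over seeds.
#'
#' @param preset an [experiment_preset()].
#' @param seeds integer vector of replicate seeds (the canonical design
#'   uses 10).
#' @param net_args extra arguments to [build_connectivity()] /
#'   [tc_network()] overrides, e.g.
#'   `list(weights = c("PY->PY/AMPA" = 0.9 * 0.24))`.
#' @param keep_records if TRUE the full `tc_record` of every seed is kept
#'   (memory-heavy).
#' @param ... passed to [simulate_network()] (e.g. `snapshot_ms`).
#' @return list of class `experiment_result`: `preset`, `per_seed`
#'   (data.frame with one row per seed and session marker), `summary`
#'   (mean and SEM of performance per marker), `replays`, `weights`
#'   (trajectories), `manifest`.
#' @export
run_preset <- function(preset, seeds = 1:10, net_args = list(),
                       keep_records = FALSE, ...) {
  design <- build_experiment(preset)
  cm <- do.call(build_connectivity,
                c(list(populations = preset$populations),
                  net_args[intersect(names(net_args),
                                     c("radii", "weights", "mini_amps"))]))
  overrides <- net_args$overrides
  rows <- list(); replays <- list(); wtraj <- list(); records <- list()
  failed <- integer(0)
  for (s in seeds) {
    rec <- tryCatch(
      simulate_network(tc_network(preset$populations, connectivity = cm,
                                  overrides = overrides),
                       design$schedule, design$sessions, seed = s, ...),
      error = function(e) e)
    if (inherits(rec, "error")) {
      failed <- c(failed, s)
      next
    }
    for (mk in names(design$markers)) {
      idx <- design$markers[[mk]]
      ss <- rec$sessions[[idx]]
      proto <- ss$protocol
      sc <- score_session(rec$raster, proto$groups, ss$onsets,
                          ideal = proto$order)
      rows[[length(rows) + 1L]] <- data.frame(
        seed = s, marker = mk,
        performance = recall_performance(sc$sm),
        mean_sm = mean(sc$sm))
    }
    # replays of Seq1 during the sleep block
    chain1 <- preset$seq1_start +
      0:(preset$group_size * 5 - 1)
    sleep_r <- raster_window(rec$raster, design$sleep_window)
    rp <- detect_replays(sleep_r, chain1, group_size = preset$group_size)
    replays[[length(replays) + 1L]] <- data.frame(
      seed = s, correct = rp$correct, reverse = rp$reverse,
      n_candidates = rp$n_candidates)
    if (length(rec$weight_times) > 1) {
      mask <- sequence_weight_mask(cm, chain1)
      wtraj[[length(wtraj) + 1L]] <-
        cbind(seed = s, weight_trajectory(rec$weight_times, rec$weights,
                                          mask))
    }
    if (keep_records) records[[as.character(s)]] <- rec
  }
  per_seed <- do.call(rbind, rows)
  summary <- NULL
  if (!is.null(per_seed)) {
    agg_m <- tapply(per_seed$performance, per_seed$marker, mean)
    agg_s <- tapply(per_seed$performance, per_seed$marker,
                    function(x) stats::sd(x) / sqrt(length(x)))
    summary <- data.frame(marker = names(agg_m), mean = as.numeric(agg_m),
                          sem = as.numeric(agg_s))
  }
  structure(list(preset = preset, per_seed = per_seed, summary = summary,
                 replays = do.call(rbind, replays),
                 weights = if (length(wtraj)) do.call(rbind, wtraj),
                 records = records,
                 manifest = list(seeds = seeds, failed = failed,
                                 partial = length(failed) > 0,
                                 scale = preset$scale,
                                 populations = preset$populations,
                                 net_args = net_args)),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>", x$preset$name,
      sprintf("(scale %.2g, %d seeds%s)\n", x$preset$scale,
              length(x$manifest$seeds),
              if (x$manifest$partial) ", PARTIAL" else ""))
  if (!is.null(x$summary)) print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Sweep a preset over a parameter grid
#'
#' Runs [run_preset()] at every grid point and collects endpoint metrics
#' in a tidy table (one row per grid point and seed).
#'
#' @param preset an [experiment_preset()] used as the template.
#' @param grid data.frame whose columns name swept preset fields
#'   (`train2_s`, `seq2_start`, `seq2_direction`, `sleep_s`) or a
#'   `mini_amp` / AMPA factor column (`ampa_factor`, `tc_kleak_factor`).
#' @param seeds replicate seeds per grid point.
#' @param ... passed to [run_preset()].
#' @return data.frame with the grid columns plus `seed`, `marker`,
#'   `performance`.
#' @export
sweep_preset <- function(preset, grid, seeds = 1:3, ...) {
  if (!nrow(grid)) stop("empty sweep grid")
  out <- list()
  for (g in seq_len(nrow(grid))) {
    p <- preset
    net_args <- list()
    for (col in names(grid)) {
      val <- grid[[col]][g]
      if (col %in% c("train2_s")) p$train2_trials <-
          max(2L, as.integer(round(val * p$scale)))
      else if (col == "seq2_start") p$seq2_start <-
          as.integer(round(val * p$populations[["PY"]] / 500))
      else if (col == "seq2_direction") p$seq2_direction <- val
      else if (col == "sleep_s") p$sleep_ms <- 1000 * val * p$scale
      else if (col == "mini_amp") net_args$mini_amps <-
          c("PY->PY/AMPA" = val, "PY->IN/AMPA" = val, "IN->PY/GABAA" = val)
      else if (col == "ampa_factor") {
        w <- default_weights()
        ampa <- grep("AMPA", names(w), value = TRUE)
        net_args$weights <- w[ampa] * val
      } else if (col == "tc_kleak_factor") net_args$overrides <-
          list(TC = list(G_KL = val * 0.024))
      else stop("unknown sweep column: ", col)
    }
    res <- run_preset(p, seeds = seeds, net_args = net_args, ...)
    if (!is.null(res$per_seed)) {
      block <- cbind(grid[rep(g, nrow(res$per_seed)), , drop = FALSE],
                     res$per_seed)
      rownames(block) <- NULL
      out[[length(out) + 1L]] <- block
    }
  }
  do.call(rbind, out)
}
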