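test_that("trajectory components are independent and speed is conserved", {
  p <- tracking_params(0.092, start_heading = 0)  # purely horizontal
  path <- generate_trajectory(p, 30, seed = 1)
  expect_equal(diff(range(path$y)), 0)  # y never changes: x/y independent
  step <- sqrt(diff(path$x)^2 + diff(path$y)^2)
  expect_equal(step, rep(p$target_speed * p$speed_px_scale, length(step)),
               tolerance = 1e-9)
  expect_true(all(path$x >= 0 & path$x <= p$arena[1]))
})

test_that("speed is conserved across wall and disc reflections", {
  p <- tracking_params(0.0920)
  path <- generate_trajectory(p, 60, seed = 21)
  step <- sqrt(diff(path$x)^2 + diff(path$y)^2)
  expect_equal(max(abs(step - p$target_speed * p$speed_px_scale)), 0,
               tolerance = 1e-9)
})

test_that("the target never enters the central protective zone", {
  # aim straight at the screen centre so the protective disc must deflect it
  p <- tracking_params(0.0920, start_heading = 3 * pi / 2)
  path <- generate_trajectory(p, 180, seed = 5)
  cx <- p$arena[1] / 2; cy <- p$arena[2] / 2
  d <- sqrt((path$x - cx)^2 + (path$y - cy)^2)
  expect_gte(min(d), p$protective_radius_cm * p$px_per_cm - 1e-9)
  expect_error(generate_trajectory(p, -1), "positive")
})

test_that("stimulus schedules respect interval bounds and determinism", {
  p <- discrimination_params(rt_window = 450)
  s <- generate_stimulus_schedule(p, 180, seed = 3)
  expect_gte(nrow(s), 60)
  expect_lte(nrow(s), 90)
  expect_true(all(diff(s$onset) %in% p$onset_intervals))
  s2 <- generate_stimulus_schedule(p, 180, seed = 3)
  expect_identical(s, s2)
  all_t <- generate_stimulus_schedule(discrimination_params(450, p_target = 1),
                                      60, seed = 4)
  expect_true(all(all_t$is_target))
})

test_that("discrimination scoring matches hand-enumerated cases", {
  p <- discrimination_params(rt_window = 500)
  sched <- tibble::tibble(onset = seq(0, by = 2500, length.out = 10),
                          stimulus = rep(1:2, 5),
                          is_target = rep(c(TRUE, FALSE), 5))
  # every target answered 100 ms after onset, no false alarms
  out <- score_discrimination(sched, sched$onset[sched$is_target] + 100, p)
  expect_equal(out$accuracy, 100)
  expect_equal(out$mean_rt, 100)
  # no responses at all: distractors correct by omission
  out <- score_discrimination(sched, numeric(0), p)
  expect_equal(out$accuracy, 50)
  expect_true(is.na(out$mean_rt))
  # 6 targets, 4 distractors; 5 hits in-window + 1 false alarm -> (5+3)/10
  sched2 <- tibble::tibble(onset = seq(0, by = 2500, length.out = 10),
                           stimulus = 1,
                           is_target = rep(c(TRUE, FALSE), c(6, 4)))
  responses <- sort(c(sched2$onset[1:5] + 200, sched2$onset[7] + 150))
  out <- score_discrimination(sched2, responses, p)
  expect_equal(out$accuracy, 80)
  # a late response misses the window
  out <- score_discrimination(sched2, sched2$onset[1] + 600, p)
  expect_equal(out$accuracy, 100 * 4 / 10)  # target 1 missed too
  expect_warning(score_discrimination(sched, -50, p), "before the first")
})

test_that("trial records stay within their contracted ranges", {
  obs <- flat_observer()
  tr <- tracking_params(0.0920)
  ds <- discrimination_params(450)
  rec <- run_trial(obs, "dual", tr, ds, duration = 180, seed = 9)
  expect_true(rec$tracking_accuracy >= 0 && rec$tracking_accuracy <= 100)
  expect_true(rec$discrimination_accuracy >= 0 &&
                rec$discrimination_accuracy <= 100)
  expect_true(is.na(rec$mean_rt) || rec$mean_rt <= ds$rt_window)
  expect_identical(rec, run_trial(obs, "dual", tr, ds, 180, seed = 9))
  single <- run_trial(obs, "single_tracking", tr, ds, 60, seed = 2)
  expect_true(is.na(single$discrimination_accuracy))
  expect_error(run_trial(obs, "dual", tr, ds, duration = 0), "positive")
})

test_that("dual-task interference lowers discrimination accuracy as configured", {
  ds <- discrimination_params(450)
  tr <- tracking_params(0.0920)
  run_means <- function(obs, condition, n = 400) {
    mean(vapply(seq_len(n), function(i) {
      dualtasksim:::run_trial_core(obs, condition, tr, ds,
                                   180)$discrimination_accuracy
    }, numeric(1)))
  }
  set.seed(31)
  obs15 <- flat_observer(interference_discrim = 15)
  gap <- run_means(obs15, "single_discrimination") - run_means(obs15, "dual")
  expect_equal(gap, 15, tolerance = 1.5)
  # no-interference limit: dual and single indistinguishable
  obs0 <- flat_observer(interference_discrim = 0, interference_track = 0)
  s <- vapply(1:400, function(i) {
    dualtasksim:::run_trial_core(obs0, "single_discrimination", tr, ds,
                                 180)$discrimination_accuracy
  }, numeric(1))
  d <- vapply(1:400, function(i) {
    dualtasksim:::run_trial_core(obs0, "dual", tr, ds,
                                 180)$discrimination_accuracy
  }, numeric(1))
  expect_gt(stats::t.test(s, d)$p.value, 0.01)
})

test_that("accuracy responds monotonically to difficulty across the ladders", {
  obs <- flat_observer()
  speeds <- build_ladder("tracking_speed")$value
  acc_track <- vapply(speeds, function(v) {
    psychometric_accuracy(obs, "tracking", v)
  }, numeric(1))
  expect_true(all(diff(acc_track) <= 0))
  windows <- build_ladder("rt_window")$value
  acc_disc <- vapply(windows, function(v) {
    psychometric_accuracy(obs, "discrimination", v)
  }, numeric(1))
  # ladder order means shrinking windows, so accuracy falls with level,
  # i.e. accuracy is non-decreasing in the window itself
  expect_true(all(diff(acc_disc) <= 0))
  # realized accuracies follow the same trend through the full engine
  set.seed(17)
  lvl <- c(5, 15, 25, 35, 45)
  realized <- vapply(speeds[lvl], function(v) {
    mean(vapply(1:40, function(i) {
      dualtasksim:::run_trial_core(obs, "single_tracking",
                                   tracking_params(v), NULL,
                                   60)$tracking_accuracy
    }, numeric(1)))
  }, numeric(1))
  expect_lt(stats::cor(realized, seq_along(lvl), method = "spearman"), 0)
})
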