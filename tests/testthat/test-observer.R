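test_that("psychometric functions are anchored at the 80% point", {
  obs <- flat_observer(lapse = 0.01)
  expect_equal(psychometric_accuracy(obs, "tracking", obs$track_midpoint), 80)
  expect_equal(
    psychometric_accuracy(obs, "discrimination", obs$discrim_midpoint), 80)
  # lapse bounds the asymptote
  expect_lte(psychometric_accuracy(obs, "tracking", 0.0001), 99)
})

test_that("interference and coordination learning shift dual accuracy", {
  obs <- flat_observer(interference_discrim = 15, learning_rate_dual = 1.2)
  at_mid <- function(...) {
    psychometric_accuracy(obs, "discrimination", obs$discrim_midpoint, ...)
  }
  expect_equal(at_mid(dual = TRUE), 65)  # 80 - 15
  # six dual-trained sessions reduce interference by 6 x 1.2 = 7.2 points
  expect_equal(at_mid(dual = TRUE, dual_sessions_completed = 6),
               80 - (15 - 7.2))
  # coordination learning never overshoots below zero interference
  expect_equal(at_mid(dual = TRUE, dual_sessions_completed = 50), 80)
})

test_that("single-skill learning moves the midpoints, not the cost", {
  obs <- observer_params(learning_track = 0.00055, learning_discrim = 4.2,
                        lapse = 0)
  base <- psychometric_accuracy(obs, "tracking", obs$track_midpoint)
  trained <- psychometric_accuracy(obs, "tracking", obs$track_midpoint,
                                   sessions_completed = 6)
  expect_gt(trained, base)
  # interference in accuracy points is invariant to the midpoint shift
  gap <- psychometric_accuracy(obs, "discrimination", obs$discrim_midpoint,
                               sessions_completed = 6) -
    psychometric_accuracy(obs, "discrimination", obs$discrim_midpoint,
                          dual = TRUE, sessions_completed = 6)
  expect_equal(gap, obs$interference_discrim)
})

test_that("population sampling respects sizes, seeds, and dispersions", {
  pop <- sample_population(population_config(), seed = 1)
  expect_length(pop, 39)
  groups <- vapply(pop, `[[`, "", "group")
  expect_identical(sum(groups == "multitask"), 19L)
  expect_identical(sum(groups == "single"), 20L)
  expect_identical(vapply(sample_population(population_config(), seed = 1),
                          `[[`, 0, "track_midpoint"),
                   vapply(pop, `[[`, 0, "track_midpoint"))
  # zero dispersion collapses everyone onto the population mean
  degenerate <- population_config(
    n_per_group = c(multitask = 3L, single = 3L),
    sds = as.list(stats::setNames(
      rep(0, 15),
      names(population_config()$means))))
  same <- sample_population(degenerate, seed = 2)
  expect_equal(length(unique(vapply(same, `[[`, 0, "track_midpoint"))), 1)
  expect_equal(same[[1]]$interference_discrim, 15.6)
  expect_error(population_config(sds = list(lapse = -1)), "non-negative")
  expect_error(population_config(means = list(nonsense = 1)), "unknown")
})

test_that("sampled observers always satisfy their parameter invariants", {
  pop <- sample_population(population_config(), seed = 99)
  for (obs in pop) {
    expect_gt(obs$track_slope, 0)
    expect_gt(obs$discrim_slope, 0)
    expect_gte(obs$lapse, 0); expect_lte(obs$lapse, 0.05)
    expect_gte(obs$interference_discrim, 0)
    expect_gte(obs$interference_track, 0)
  }
})

test_that("group randomization is independent of observer parameters", {
  pop <- sample_population(
    population_config(n_per_group = c(multitask = 150L, single = 150L)),
    seed = 5)
  mids <- vapply(pop, `[[`, 0, "track_midpoint")
  groups <- vapply(pop, `[[`, "", "group")
  tt <- independent_t(mids[groups == "multitask"], mids[groups == "single"])
  expect_lt(abs(tt$t), 4)
})

test_that("transfer tables have the configured trial geometry", {
  obs <- sample_population(population_config(
    n_per_group = c(multitask = 1L, single = 1L)), seed = 3)[[1]]
  tabs <- generate_transfer_tables(obs, transfer_effect_params(), "pre",
                                   seed = 4)
  expect_identical(nrow(tabs$prp), 160L)        # 4 blocks x 40
  expect_identical(nrow(tabs$single_rs), 144L)  # 4 x 36
  expect_identical(nrow(tabs$stroop), 144L)
  expect_identical(nrow(tabs$ab), 96L)          # 4 x 24
  expect_identical(nrow(tabs$gonogo), 144L)
  expect_identical(nrow(tabs$flanker), 144L)
  expect_identical(sum(tabs$prp$soa == 200), 80L)
  expect_identical(sum(!tabs$gonogo$go), 36L)   # 25% no-go
  expect_identical(as.vector(table(tabs$ab$lag)), rep(24L, 4))
  expect_identical(as.vector(table(tabs$stroop$trial_type)), rep(48L, 3))
  expect_identical(
    tabs$prp,
    generate_transfer_tables(obs, transfer_effect_params(), "pre",
                             seed = 4)$prp)
})

test_that("generated transfer effects match their configured parameters", {
  obs <- flat_observer()
  obs$transfer <- list(prp_effect = 213, ab_magnitude = 0,
                       stroop_effect = 122, flanker_effect = 92,
                       commission_rate = 25, go_rt = 318, rs_rt = 631)
  eff <- transfer_effect_params()
  set.seed(8)
  reps <- lapply(1:60, function(i) {
    generate_transfer_tables(obs, eff, "pre")
  })
  prp <- mean(vapply(reps, function(t) prp_effect(t$prp), numeric(1)))
  expect_equal(prp, 213, tolerance = 10)
  ab <- mean(vapply(reps, function(t) ab_magnitude(t$ab), numeric(1)))
  expect_lt(abs(ab), 4)
  com <- mean(vapply(reps, function(t) {
    gonogo_stats(t$gonogo)$commission_rate
  }, numeric(1)))
  expect_equal(com, 25, tolerance = 3)
})

test_that("observers achieve near-criterion accuracy at their chosen levels", {
  rec <- staircase_recovery_study(n_observers = 40, kind = "tracking_speed",
                                  seed = 6)
  expect_gte(mean(rec$true_accuracy), 77)
  expect_lte(mean(rec$true_accuracy), 83)
  expect_lte(stats::median(abs(rec$true_accuracy - 80)), 4)
})
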