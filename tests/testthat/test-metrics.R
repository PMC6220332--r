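test_that("cost summaries satisfy the defining identities", {
  tr <- test_trials(80.70, 82.18, 85.13, 67.79, 323.71, 339.52)
  cs <- compute_costs(tr)
  expect_equal(cs$tracking_cost, cs$single_tracking - cs$dual_tracking)
  expect_equal(cs$discrim_cost, cs$single_discrim - cs$dual_discrim)
  expect_equal(cs$rt_cost, cs$dual_rt - cs$single_rt)
  expect_equal(cs$overall_cost, cs$tracking_cost + cs$discrim_cost)
  # identical single and dual performance: every cost is zero
  zero <- compute_costs(test_trials(80, 80, 85, 85, 320, 320))
  expect_equal(zero$tracking_cost, 0)
  expect_equal(zero$discrim_cost, 0)
  expect_equal(zero$rt_cost, 0)
  expect_equal(zero$overall_cost, 0)
  # a missing condition is an error naming that condition
  expect_error(compute_costs(tr[tr$condition != "dual", ]), "dual")
})

test_that("cohort-level costs agree with the per-participant computation", {
  cohort <- tiny_cohort(seed = 3)
  costs <- cohort_costs(cohort$trials)
  expect_identical(nrow(costs), 8L)  # 4 participants x 2 sessions
  for (i in seq_len(nrow(costs))) {
    sel <- cohort$trials$participant_id == costs$participant_id[i] &
      cohort$trials$phase == as.character(costs$session[i])
    ref <- compute_costs(cohort$trials[sel, ])
    for (col in names(ref)) {
      expect_equal(costs[[col]][i], ref[[col]], tolerance = 1e-12)
    }
  }
  # identities re-asserted after aggregation
  expect_equal(costs$overall_cost, costs$tracking_cost + costs$discrim_cost)
})

test_that("transfer statistics match hand-listed examples", {
  prp <- tibble::tibble(soa = rep(c(200, 1000), each = 3),
                        rt2 = c(650, 610, 600, 420, 400, 380),
                        correct2 = TRUE)
  expect_equal(prp_effect(prp), 220)
  expect_equal(prp_effect(dplyr::mutate(prp, rt2 = 500)), 0)
  expect_error(prp_effect(dplyr::mutate(prp, correct2 = soa == 200)), "SOA")

  # per-lag T2|T1 accuracies exactly 55/65/82/78 -> (80) - (60) = 20
  ab <- tibble::tibble(
    lag = rep(c(2, 3, 5, 7), each = 100),
    t1_correct = TRUE,
    t2_correct = unlist(lapply(c(55, 65, 82, 78), function(k) {
      rep(c(TRUE, FALSE), c(k, 100 - k))
    })))
  expect_equal(ab_magnitude(ab), 20)
  flat <- dplyr::mutate(ab, t2_correct = TRUE)
  expect_equal(ab_magnitude(flat), 0)
  expect_error(ab_magnitude(dplyr::mutate(ab, t1_correct = lag != 5)),
               "lag 5")

  st <- tibble::tibble(
    trial_type = rep(c("congruent", "incongruent", "neutral"), each = 2),
    rt = c(500, 520, 640, 660, 800, 900), correct = TRUE)
  expect_equal(congruency_effect(st, "stroop"), 140)  # neutral excluded
  expect_error(congruency_effect(st[st$trial_type == "neutral", ], "flanker"))

  gng <- tibble::tibble(go = rep(c(TRUE, FALSE), c(120, 40)),
                        responded = rep(c(TRUE, TRUE, FALSE),
                                        c(120, 7, 33)),
                        rt = c(rep(300, 120), rep(NA, 40)))
  out <- gonogo_stats(gng)
  expect_equal(out$commission_rate, 17.5)
  expect_equal(out$go_rt, 300)
  expect_equal(gonogo_stats(tibble::tibble(
    go = rep(c(TRUE, FALSE), c(108, 36)),
    responded = rep(c(TRUE, FALSE), c(117, 27)),
    rt = 300))$commission_rate, 25)
  expect_error(gonogo_stats(gng[gng$go, ]), "no-go")
})

test_that("RT contrasts are translation-equivariant", {
  cohort <- tiny_cohort(seed = 5)
  shift <- 137
  shifted <- cohort$transfer
  shifted$prp$rt2 <- shifted$prp$rt2 + shift
  shifted$stroop$rt <- shifted$stroop$rt + shift
  shifted$flanker$rt <- shifted$flanker$rt + shift
  a <- transfer_summary(cohort$transfer)
  b <- transfer_summary(shifted)
  expect_equal(b$prp_effect, a$prp_effect)
  expect_equal(b$stroop_effect, a$stroop_effect)
  expect_equal(b$flanker_effect, a$flanker_effect)
  expect_equal(b$ab_magnitude, a$ab_magnitude)
})

test_that("cohort transfer summaries agree with the scalar statistics", {
  cohort <- tiny_cohort(seed = 11)
  summ <- transfer_summary(cohort$transfer)
  expect_identical(nrow(summ), 8L)
  for (i in c(1, 4, 6)) {
    pid <- summ$participant_id[i]
    ses <- as.character(summ$session[i])
    pick <- function(task) {
      t <- cohort$transfer[[task]]
      t[t$participant_id == pid & t$session == ses, ]
    }
    expect_equal(summ$prp_effect[i], prp_effect(pick("prp")))
    expect_equal(summ$ab_magnitude[i], ab_magnitude(pick("ab")))
    expect_equal(summ$stroop_effect[i],
                 congruency_effect(pick("stroop"), "stroop"))
    expect_equal(summ$flanker_effect[i],
                 congruency_effect(pick("flanker"), "flanker"))
    gs <- gonogo_stats(pick("gonogo"))
    expect_equal(summ$commission_rate[i], gs$commission_rate)
    expect_equal(summ$go_rt[i], gs$go_rt)
    rs <- pick("single_rs")
    expect_equal(summ$single_rs_rt[i], mean(rs$rt[rs$correct]))
  }
  expect_true(all(summ$ab_magnitude >= -100 & summ$ab_magnitude <= 100))
  expect_true(all(summ$commission_rate >= 0 & summ$commission_rate <= 100))
})

test_that("the 3-SD exclusion rule flags planted outliers only", {
  cohort <- run_cohort(
    population_config(n_per_group = c(multitask = 6L, single = 6L)),
    protocol_config(include_training = FALSE), seed = 13)
  clean <- apply_exclusions(cohort$transfer)
  expect_identical(nrow(clean$excluded), 0L)
  expect_length(clean$retained, 12)

  # plant a slow-RT outlier on single response selection
  slow <- cohort$transfer
  victim <- clean$retained[1]
  sel <- slow$single_rs$participant_id == victim &
    slow$single_rs$session == "pre"
  slow$single_rs$rt[sel] <- slow$single_rs$rt[sel] + 3000
  out <- apply_exclusions(slow)
  expect_true(victim %in% out$excluded$participant_id)
  expect_match(out$excluded$reason[out$excluded$participant_id == victim],
               "single_rs")

  # plant a low-accuracy outlier on one task only ("one or more" rule)
  low <- cohort$transfer
  victim2 <- clean$retained[2]
  sel2 <- low$prp$participant_id == victim2 & low$prp$session == "pre"
  low$prp$correct2[sel2] <- rep(c(TRUE, FALSE), c(16, sum(sel2) - 16))
  out2 <- apply_exclusions(low)
  expect_true(victim2 %in% out2$excluded$participant_id)

  # non-completers are excluded regardless of performance
  out3 <- apply_exclusions(cohort$transfer,
                           completed = setdiff(clean$retained, victim))
  expect_true(victim %in% out3$excluded$participant_id)
  expect_error(apply_exclusions(lapply(cohort$transfer, function(t) {
    t[t$participant_id %in% clean$retained[1:2], ]
  })), "too small")
})
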