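#' Staircase parameter-recovery study
#'
#' Validates the thresholding procedure by simulation: observers with known
#' logistic psychometric functions (80% points dispersed across the ladder)
#' are run through the nine-trial adaptive staircase and the regression
#' selection, and the accuracy actually achieved at each chosen level is
#' measured -- both in closed form from the generative psychometric
#' function and empirically over fresh trials at the chosen level.
#'
#' @param n_observers Number of simulated observers.
#' @param kind Ladder to threshold (`"tracking_speed"` or `"rt_window"`).
#' @param population A [population_config()] to draw observers from.
#' @param cfg A [staircase_config()].
#' @param duration Thresholding trial length (s).
#' @param n_fresh_trials Fresh measurement trials at the chosen level.
#' @param seed Integer seed.
#' @return A tibble with one row per observer: `chosen_level`, `true_accuracy`
#'   (closed-form accuracy at the chosen level), `fresh_accuracy` (mean over
#'   fresh simulated trials).
#' @export
staircase_recovery_study <- function(n_observers = 200,
                                     kind = c("tracking_speed", "rt_window"),
                                     population = population_config(),
                                     cfg = staircase_config(),
                                     duration = NULL,
                                     n_fresh_trials = 10, seed = 1L) {
  kind <- match.arg(kind)
  ladder <- build_ladder(kind)
  duration <- duration %||% if (kind == "tracking_speed") 60 else 120
  pop <- population_config(n_per_group = c(multitask = ceiling(n_observers / 2),
                                           single = floor(n_observers / 2)),
                           means = population$means, sds = population$sds,
                           transfer = population$transfer)
  observers <- sample_population(pop, seed = derive_seed(seed, "recovery/pop"))
  observers <- observers[seq_len(n_observers)]
  runner <- if (kind == "tracking_speed") {
    function(obs, value, dur) {
      run_trial_core(obs, "single_tracking", tracking_params(value), NULL,
                     dur)$tracking_accuracy
    }
  } else {
    function(obs, value, dur) {
      run_trial_core(obs, "single_discrimination", NULL,
                     discrimination_params(value), dur)$discrimination_accuracy
    }
  }
  task <- if (kind == "tracking_speed") "tracking" else "discrimination"
  rows <- lapply(seq_along(observers), function(i) {
    obs <- observers[[i]]
    th <- run_threshold_phase(obs, ladder, cfg, runner, duration,
                              seed = derive_seed(seed, paste0("recovery/", i)))
    value <- ladder_value(ladder, th$chosen_level)
    true_acc <- psychometric_accuracy(obs, task, value)
    set.seed(derive_seed(seed, paste0("recovery/fresh/", i)))
    fresh <- mean(vapply(seq_len(n_fresh_trials), function(j) {
      runner(obs, value, duration)
    }, numeric(1)))
    list(chosen_level = th$chosen_level, true_accuracy = true_acc,
         fresh_accuracy = fresh)
  })
  rows_to_tibble(rows)
}

# Per-participant wide table of a cohort cost measure, ready for
# mixed_anova_2x2().
costs_wide <- function(costs, measure = "overall_cost") {
  costs |>
    dplyr::select("participant_id", "group", "session",
                  value = dplyr::all_of(measure)) |>
    tidyr::pivot_wider(names_from = "session", values_from = "value")
}

#' Replicated training-effect study
#'
#' Simulates many independent cohorts through thresholding, pre-test, and
#' post-test (training trials are causally inert in the observer model and
#' are skipped; learning is applied by session count) and records the
#' session-by-group interaction test on the overall dual-task cost for each
#' replicate.
#'
#' @param n_replicates Number of simulated cohorts.
#' @param population A [population_config()].
#' @param protocol A [protocol_config()]; transfer and training default off
#'   here.
#' @param seed Integer seed.
#' @return A tibble with one row per replicate: interaction `F`, `p`,
#'   `partial_eta_sq`, and the two groups' mean pre-to-post cost changes.
#' @export
simulate_training_effect_study <- function(n_replicates = 500,
                                           population = population_config(),
                                           protocol = protocol_config(
                                             include_training = FALSE,
                                             include_transfer = FALSE),
                                           seed = 1L) {
  rows <- lapply(seq_len(n_replicates), function(r) {
    cohort <- run_cohort(population, protocol,
                         seed = derive_seed(seed, paste0("effect/", r)))
    wide <- costs_wide(cohort_costs(cohort$trials))
    an <- mixed_anova_2x2(wide)
    inter <- an[an$effect == "interaction", ]
    ch <- tapply(wide$post - wide$pre, wide$group, mean)
    list(replicate = r, F = inter$F, p = inter$p,
         partial_eta_sq = inter$partial_eta_sq,
         change_multitask = unname(ch["multitask"]),
         change_single = unname(ch["single"]))
  })
  rows_to_tibble(rows)
}

#' Replicated transfer-null study
#'
#' Simulates many independent cohorts' transfer batteries (pre and post)
#' and records, for each replicate and each of the six transfer statistics,
#' the session-by-group interaction p-value. Under the default generative
#' parameters the practice shift is identical across groups, so every
#' statistic's interaction is null in expectation and the rejection rate
#' should sit near the nominal level.
#'
#' @param n_replicates Number of simulated cohorts.
#' @param population A [population_config()].
#' @param seed Integer seed.
#' @return A tibble with one row per replicate and measure: `p`, `F`.
#' @export
simulate_transfer_null_study <- function(n_replicates = 150,
                                         population = population_config(),
                                         seed = 1L) {
  measures <- c("prp_effect", "single_rs_rt", "stroop_effect",
                "ab_magnitude", "flanker_effect", "commission_rate", "go_rt")
  rows <- list()
  for (r in seq_len(n_replicates)) {
    observers <- sample_population(
      population, seed = derive_seed(seed, paste0("transfer/pop/", r)))
    tabs <- lapply(observers, function(obs) {
      pre <- generate_transfer_tables(
        obs, population$transfer, "pre",
        seed = derive_seed(seed, paste0("transfer/", r, "/", obs$id, "/pre")))
      post <- generate_transfer_tables(
        obs, population$transfer, "post",
        seed = derive_seed(seed, paste0("transfer/", r, "/", obs$id, "/post")))
      mapply(dplyr::bind_rows, pre, post, SIMPLIFY = FALSE)
    })
    long <- lapply(names(tabs[[1]]), function(task) {
      dplyr::bind_rows(lapply(tabs, `[[`, task))
    })
    names(long) <- names(tabs[[1]])
    summ <- transfer_summary(long)
    for (ms in measures) {
      wide <- summ |>
        dplyr::select("participant_id", "group", "session",
                      value = dplyr::all_of(ms)) |>
        tidyr::pivot_wider(names_from = "session", values_from = "value")
      an <- mixed_anova_2x2(wide)
      inter <- an[an$effect == "interaction", ]
      rows[[length(rows) + 1]] <- list(replicate = r, measure = ms,
                                       F = inter$F, p = inter$p)
    }
  }
  rows_to_tibble(rows)
}
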