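# Shared fixtures, built in code.

# An observer with no individual quirks: zero lapse-free noise sources where
# possible, fixed interference, no learning unless asked for.
flat_observer <- function(...) {
  defaults <- list(id = "obs", group = "multitask", lapse = 0,
                   false_alarm_rate = 0, learning_track = 0,
                   learning_discrim = 0, learning_rate_dual = 0)
  do.call(observer_params, utils::modifyList(defaults, list(...)))
}

# Test trials for one participant/session from per-condition means
# (constant across the five trials, so condition means equal the inputs).
test_trials <- function(single_tracking, dual_tracking, single_discrim,
                        dual_discrim, single_rt = 320, dual_rt = 335,
                        n = 5) {
  tibble::tibble(
    condition = rep(c("single_tracking", "single_discrimination", "dual"),
                    each = n),
    tracking_accuracy = c(rep(single_tracking, n), rep(NA, n),
                          rep(dual_tracking, n)),
    discrimination_accuracy = c(rep(NA, n), rep(single_discrim, n),
                                rep(dual_discrim, n)),
    mean_rt = c(rep(NA, n), rep(single_rt, n), rep(dual_rt, n)))
}

# Random 2x2 mixed-design dataset.
random_design <- function(n1, n2, effect = 0) {
  g <- rep(c("a", "b"), c(n1, n2))
  pre <- stats::rnorm(n1 + n2, 10, 2)
  post <- pre + stats::rnorm(n1 + n2, 0, 2) + effect * (g == "a")
  data.frame(group = g, pre = pre, post = post)
}

# A tiny cohort shared by several test files (2 + 2 participants, full
# protocol including transfer).
tiny_cohort <- function(seed = 42) {
  run_cohort(population_config(n_per_group = c(multitask = 2L, single = 2L)),
             protocol_config(), seed = seed)
}
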