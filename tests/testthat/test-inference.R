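test_that("degenerate designs produce exactly null effects", {
  d <- random_design(8, 8)
  d$post <- d$pre
  an <- mixed_anova_2x2(d)
  expect_equal(an$F[an$effect == "session"], 0)
  expect_equal(an$F[an$effect == "interaction"], 0)
  # constant group shift with identical pre-to-post change: no interaction
  # (integer-valued data keep the arithmetic exact)
  set.seed(2)
  d2 <- data.frame(group = rep(c("a", "b"), c(6, 9)),
                   pre = sample(5:30, 15, replace = TRUE))
  d2$post <- d2$pre + 3
  d2$pre <- d2$pre + 5 * (d2$group == "a")
  d2$post <- d2$post + 5 * (d2$group == "a")
  an2 <- mixed_anova_2x2(d2)
  expect_equal(an2$F[an2$effect == "interaction"], 0)
  expect_error(mixed_anova_2x2(data.frame(group = "a", pre = 1, post = 2)),
               "two levels")
})

test_that("the closed-form ANOVA matches aov() on balanced designs", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(c(6, 10, 14), 1)
    d <- random_design(n, n, effect = stats::runif(1, -3, 3))
    an <- mixed_anova_2x2(d)
    long <- data.frame(id = factor(rep(seq_len(2 * n), 2)),
                       group = factor(rep(d$group, 2)),
                       session = factor(rep(c("pre", "post"), each = 2 * n)),
                       y = c(d$pre, d$post))
    av <- summary(stats::aov(y ~ group * session + Error(id / session),
                             data = long))
    between <- av[["Error: id"]][[1]]
    within <- av[["Error: id:session"]][[1]]
    expect_equal(an$F[an$effect == "group"], between["group", "F value"],
                 tolerance = 1e-8)
    expect_equal(an$F[an$effect == "session"], within["session", "F value"],
                 tolerance = 1e-8)
    expect_equal(an$F[an$effect == "interaction"],
                 within["group:session", "F value"], tolerance = 1e-8)
    expect_equal(an$p[an$effect == "interaction"],
                 within["group:session", "Pr(>F)"], tolerance = 1e-8)
  }
})

test_that("interaction F equals the squared pooled t on change scores", {
  set.seed(22)
  for (i in 1:200) {
    n1 <- sample(3:25, 1); n2 <- sample(3:25, 1)
    d <- random_design(n1, n2, effect = stats::rnorm(1))
    an <- mixed_anova_2x2(d)
    delta <- d$post - d$pre
    tt <- stats::t.test(delta[d$group == "a"], delta[d$group == "b"],
                        var.equal = TRUE)
    expect_equal(an$F[an$effect == "interaction"],
                 unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(an$df2[1], n1 + n2 - 2L)
  }
})

test_that("sums of squares decompose the total exactly", {
  set.seed(23)
  for (i in 1:50) {
    d <- random_design(sample(3:20, 1), sample(3:20, 1))
    ss <- attr(mixed_anova_2x2(d), "ss")
    expect_equal(ss$group + ss$subjects_within_group +
                   ss$within_model_sequential + ss$within_error,
                 ss$total, tolerance = 1e-9)
    an <- mixed_anova_2x2(d)
    expect_true(all(an$partial_eta_sq >= 0 & an$partial_eta_sq <= 1))
    expect_true(all(an$F >= 0))
  }
})

test_that("pooled t tests match the closed form and the design's df", {
  set.seed(24)
  x <- stats::rnorm(19); y <- stats::rnorm(20)
  out <- independent_t(x, y)
  expect_identical(out$df, 37)
  sp2 <- ((19 - 1) * stats::var(x) + (20 - 1) * stats::var(y)) / 37
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 19 + 1 / 20))
  expect_equal(out$t, t_hand, tolerance = 1e-12)
  same <- independent_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
})

test_that("BIC Bayes factors obey the penalty and transitivity identities", {
  # identical likelihoods: each extra parameter favours the simpler model
  # by a factor exp(log(n)/2)
  n <- 40
  bf <- bf_bic(-2 * (-100) + 2 * log(n), -2 * (-100) + 3 * log(n),
               -2 * (-100) + 4 * log(n))
  expect_equal(bf$bf10, exp(-log(n) / 2))
  expect_equal(bf$bf12, exp(log(n) / 2))
  bf2 <- bf_bic(-100, -100, -100, loglik = TRUE, k = c(2, 3, 4), n = n)
  expect_equal(bf2$bf10, exp(-log(n) / 2))
  expect_error(bf_bic(-100, -100, -100, loglik = TRUE, k = c(3, 3, 4), n = n),
               "nested")
  # arbitrary inputs: bf12 * bf20 == bf10 exactly
  bf3 <- bf_bic(103.2, 99.1, 101.7)
  expect_identical(bf3$bf12 * bf3$bf20, bf3$bf10)
  # bf10 = 6 and bf20 = 3 compose to bf12 = 2 by transitivity
  bf4 <- bf_bic(2 * log(6), 0, 2 * log(6) - 2 * log(3))
  expect_equal(bf4$bf10, 6)
  expect_equal(bf4$bf20, 3)
  expect_equal(bf4$bf12, 2)
})

test_that("mixed-model Bayes factors are positive and transitive", {
  set.seed(25)
  d <- random_design(10, 12, effect = 1)
  bf <- bf_mixed_anova(d)
  expect_true(bf$bf10 > 0 && bf$bf20 > 0 && bf$bf12 > 0)
  expect_equal(bf$bf12 * bf$bf20, bf$bf10, tolerance = 1e-12)
  # a strong planted interaction should favour the interaction model
  d$post[d$group == "a"] <- d$post[d$group == "a"] - 50
  bf_strong <- bf_mixed_anova(d)
  expect_lt(bf_strong$bf12, 1)
})

test_that("design tables report cell summaries and identities", {
  set.seed(26)
  cohort <- tiny_cohort(seed = 19)
  costs <- cohort_costs(cohort$trials)
  tables <- reproduce_design_tables(costs)
  tab <- tables$training_by_group
  expect_true(all(c("overall_cost", "tracking_cost", "discrim_cost") %in%
                    tab$measure))
  cell <- function(ms) tab$summary[[which(tab$measure == ms)]]
  # identity holds in every emitted row of cell means
  expect_equal(cell("overall_cost")$pre_mean,
               cell("tracking_cost")$pre_mean +
                 cell("discrim_cost")$pre_mean)
  expect_equal(cell("overall_cost")$post_mean,
               cell("tracking_cost")$post_mean +
                 cell("discrim_cost")$post_mean)
  # single participant per group: SDs suppressed with a message
  solo_ids <- c(costs$participant_id[costs$group == "multitask"][1],
                costs$participant_id[costs$group == "single"][1])
  solo <- costs[costs$participant_id %in% solo_ids, ]
  expect_message(reproduce_design_tables(solo), "suppressed")
})
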