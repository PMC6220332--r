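#' Two-by-two mixed-design ANOVA
#'
#' Exact cell-means decomposition for a design with one two-level
#' between-subject factor (group, possibly unequal sizes) and one two-level
#' within-subject factor (session). The group effect is tested on subject
#' means; session and the session-by-group interaction are tested on
#' within-subject difference scores with unweighted (Type III style)
#' contrasts, so that with unequal group sizes each group contributes
#' equally to the session contrast. For this design the interaction F is
#' identically the squared pooled two-sample t statistic on the difference
#' scores. Partial eta squared is `SS_effect / (SS_effect + SS_error)` with
#' the error stratum matching the effect.
#'
#' @param data A data frame with columns `group` (two levels), `pre`, and
#'   `post` (one row per participant).
#' @return A tibble with one row per effect (`group`, `session`,
#'   `interaction`): `F`, `df1`, `df2`, `p`, `partial_eta_sq`. The sums of
#'   squares (including the sequential within-subject decomposition, which
#'   conserves the total SS exactly) are attached as attribute `"ss"`.
#' @export
#' @examples
#' d <- data.frame(group = rep(c("a", "b"), each = 4),
#'                 pre = c(10, 12, 11, 13, 9, 11, 10, 12),
#'                 post = c(8, 9, 9, 10, 9, 11, 10, 12))
#' mixed_anova_2x2(d)
mixed_anova_2x2 <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("group", "pre", "post") %in% names(data)))
  if (anyNA(data$pre) || anyNA(data$post)) {
    stop("every participant needs both a pre and a post value", call. = FALSE)
  }
  g <- factor(data$group)
  if (nlevels(g) != 2) stop("group must have exactly two levels", call. = FALSE)
  n <- tabulate(g)
  if (any(n < 2)) stop("need at least 2 participants per group", call. = FALSE)
  N <- sum(n)
  m <- (data$pre + data$post) / 2       # subject means
  d <- data$post - data$pre             # difference scores
  mbar <- tapply(m, g, mean)
  dbar <- tapply(d, g, mean)
  gm <- mean(m)

  # between-subject stratum (2 observations per subject)
  ss_group <- 2 * sum(n * (mbar - gm)^2)
  ss_subj <- 2 * sum((m - mbar[g])^2)

  # within-subject stratum; contrast coefficients (-1, +1) have norm^2 = 2
  inv_n <- sum(1 / n)
  ss_session <- 2 * mean(dbar)^2 / inv_n          # unweighted session contrast
  ss_inter <- unname(diff(dbar))^2 / (2 * inv_n)
  ss_err_w <- sum((d - dbar[g])^2) / 2
  # sequential (weighted) within pieces, which sum exactly with the error
  ss_within_model_seq <- sum(n * dbar^2) / 2
  ss_total <- sum((c(data$pre, data$post) - mean(c(data$pre, data$post)))^2)

  df2 <- N - 2L
  eff <- function(effect, ss, ss_err) {
    # degenerate error strata: no effect and no error is a null effect
    f <- if (ss_err == 0) {
      if (ss == 0) 0 else Inf
    } else {
      (ss / 1) / (ss_err / df2)
    }
    pes <- if (ss == 0 && ss_err == 0) 0 else ss / (ss + ss_err)
    tibble::tibble(effect = effect, F = f, df1 = 1L, df2 = df2,
                   p = stats::pf(f, 1, df2, lower.tail = FALSE),
                   partial_eta_sq = pes)
  }
  out <- dplyr::bind_rows(eff("group", ss_group, ss_subj),
                          eff("session", ss_session, ss_err_w),
                          eff("interaction", ss_inter, ss_err_w))
  attr(out, "ss") <- list(
    total = ss_total, group = ss_group, subjects_within_group = ss_subj,
    session = ss_session, interaction = ss_inter,
    within_model_sequential = ss_within_model_seq, within_error = ss_err_w)
  out
}

#' Pooled-variance independent-samples t test
#'
#' Thin wrapper around [stats::t.test()]. Pooled variance is the default so
#' that with groups of 19 and 20 the degrees of freedom are 37, the
#' convention of classical mixed-design reporting.
#'
#' @param x,y Numeric vectors.
#' @param var_equal Pool the variances (default) or use Welch's correction.
#' @return A list with `t`, `df`, `p`.
#' @export
independent_t <- function(x, y, var_equal = TRUE) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (var_equal && stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = length(x) + length(y) - 2L, p = 1))
    }
    stop("zero variance in both groups with unequal means", call. = FALSE)
  }
  ht <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Bayes factors from BIC values
#'
#' Approximates the Bayes factor between nested models fitted to the same
#' data by `exp((BIC_simpler - BIC_complex) / 2)` (the unit-information
#' prior approximation). `bf10` compares the main-effects model against the
#' null, `bf20` the main-effects-plus-interaction model against the null,
#' and `bf12 = bf10 / bf20` by transitivity: values above 1 favour the
#' main-effects model over the model that adds the interaction.
#'
#' @param bic_null,bic_main,bic_interaction BIC values of the three nested
#'   fits, or (if `loglik = TRUE`) their maximised log-likelihoods together
#'   with `k` and `n`.
#' @param loglik Interpret inputs as log-likelihoods.
#' @param k Integer vector of parameter counts (null, main, interaction);
#'   required with `loglik = TRUE`.
#' @param n Number of observations; required with `loglik = TRUE`.
#' @return A list with `bf10`, `bf20`, `bf12`.
#' @export
#' @examples
#' bf_bic(100, 95, 97)          # bf10 = e^2.5, bf20 = e^1.5, bf12 = e^1
bf_bic <- function(bic_null, bic_main, bic_interaction, loglik = FALSE,
                   k = NULL, n = NULL) {
  if (loglik) {
    if (is.null(k) || is.null(n) || length(k) != 3) {
      stop("with loglik = TRUE supply k (length 3) and n", call. = FALSE)
    }
    if (any(diff(k) <= 0)) {
      stop("models must be strictly nested (increasing parameter counts)",
           call. = FALSE)
    }
    bics <- -2 * c(bic_null, bic_main, bic_interaction) + k * log(n)
    bic_null <- bics[1]; bic_main <- bics[2]; bic_interaction <- bics[3]
  }
  bf10 <- exp((bic_null - bic_main) / 2)
  bf20 <- exp((bic_null - bic_interaction) / 2)
  list(bf10 = bf10, bf20 = bf20, bf12 = bf10 / bf20)
}

#' BIC-approximated Bayes factors for the 2x2 mixed design
#'
#' Fits three nested linear mixed models by maximum likelihood with a
#' random intercept per participant -- null (intercept only), main effects
#' (session + group), and main effects plus the session-by-group
#' interaction -- and converts their BICs to Bayes factors with
#' [bf_bic()]. These are directionally comparable to, but not numerically
#' the same as, default-prior Bayesian ANOVA factors.
#'
#' @inheritParams mixed_anova_2x2
#' @return A list with `bf10`, `bf20`, `bf12`.
#' @export
bf_mixed_anova <- function(data) {
  stopifnot(all(c("group", "pre", "post") %in% names(data)))
  long <- data.frame(
    id = factor(rep(seq_len(nrow(data)), 2)),
    group = factor(rep(data$group, 2)),
    session = factor(rep(c("pre", "post"), each = nrow(data)),
                     levels = c("pre", "post")),
    value = c(data$pre, data$post))
  ctl <- lme4::lmerControl(check.conv.singular = "ignore")
  fit <- function(formula) {
    suppressMessages(lme4::lmer(formula, data = long, REML = FALSE,
                                control = ctl))
  }
  m0 <- fit(value ~ 1 + (1 | id))
  m1 <- fit(value ~ session + group + (1 | id))
  m2 <- fit(value ~ session * group + (1 | id))
  bf_bic(stats::BIC(m0), stats::BIC(m1), stats::BIC(m2))
}

#' Group-by-session summary tables with inferential statistics
#'
#' Emits the study's standard reporting layout from simulated cohort
#' metrics: per-measure group-by-session means and SDs, the baseline group
#' comparison (pooled t on the pre-training values), the mixed-ANOVA
#' interaction with partial eta squared, and the transitive Bayes factor
#' `bf12`. With a single participant per group SDs are undefined and
#' reported as `NA` with a message.
#'
#' @param costs A [cohort_costs()] tibble.
#' @param transfer_summaries Optional [transfer_summary()] tibble.
#' @return A list of tibbles: `training_by_group` (one row per cost/accuracy
#'   measure) and, when transfer summaries are given, `transfer_by_group`.
#' @export
reproduce_design_tables <- function(costs, transfer_summaries = NULL) {
  measure_table <- function(df, measures) {
    dplyr::bind_rows(lapply(measures, function(ms) {
      wide <- df |>
        dplyr::select("participant_id", "group", "session",
                      value = dplyr::all_of(ms)) |>
        tidyr::pivot_wider(names_from = "session", values_from = "value")
      if (min(table(wide$group)) < 2) {
        message("single participant in a group: SDs and tests suppressed for ",
                ms)
        cell <- wide |>
          dplyr::group_by(.data$group) |>
          dplyr::summarise(pre_mean = mean(.data$pre),
                           post_mean = mean(.data$post), .groups = "drop")
        return(tibble::tibble(measure = ms,
                              summary = list(cell)))
      }
      an <- mixed_anova_2x2(wide)
      inter <- an[an$effect == "interaction", ]
      groups <- sort(unique(wide$group))
      bt <- independent_t(wide$pre[wide$group == groups[1]],
                          wide$pre[wide$group == groups[2]])
      bf <- bf_mixed_anova(wide)
      cell <- wide |>
        dplyr::group_by(.data$group) |>
        dplyr::summarise(pre_mean = mean(.data$pre),
                         pre_sd = stats::sd(.data$pre),
                         post_mean = mean(.data$post),
                         post_sd = stats::sd(.data$post), .groups = "drop")
      tibble::tibble(measure = ms, summary = list(cell),
                     baseline_t = bt$t, baseline_p = bt$p,
                     interaction_F = inter$F, interaction_p = inter$p,
                     interaction_pes = inter$partial_eta_sq,
                     bf12 = bf$bf12)
    }))
  }
  cost_measures <- c("overall_cost", "tracking_cost", "discrim_cost",
                     "rt_cost", "single_tracking", "dual_tracking",
                     "single_discrim", "dual_discrim", "single_rt", "dual_rt")
  out <- list(training_by_group = measure_table(costs, cost_measures))
  if (!is.null(transfer_summaries)) {
    tr_measures <- c("single_rs_rt", "ab_magnitude", "prp_effect",
                     "stroop_effect", "flanker_effect", "commission_rate",
                     "go_rt")
    out$transfer_by_group <- measure_table(transfer_summaries, tr_measures)
  }
  out
}
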