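#' Dual-task cost summary for one participant and session
#'
#' Averages the test trials of each condition and derives the dual-task
#' costs. Accuracy costs are single minus dual, so a positive cost is an
#' impairment; the RT cost is dual minus single (responding is slower under
#' load). The overall cost is the sum of the tracking and discrimination
#' accuracy costs, with smaller values indicating better multitasking.
#'
#' @param trials Trial records (one participant, one test session) with
#'   columns `condition`, `tracking_accuracy`, `discrimination_accuracy`,
#'   `mean_rt`.
#' @return A one-row tibble: per-condition means, `tracking_cost`,
#'   `discrim_cost`, `rt_cost`, `overall_cost`.
#' @export
#' @examples
#' tr <- tibble::tibble(
#'   condition = c("single_tracking", "single_discrimination", "dual"),
#'   tracking_accuracy = c(80.70, NA, 82.18),
#'   discrimination_accuracy = c(NA, 85.13, 67.79),
#'   mean_rt = c(NA, 323.71, 339.52))
#' compute_costs(tr)$overall_cost  # 15.86
compute_costs <- function(trials) {
  stopifnot(is.data.frame(trials))
  for (cond in c("single_tracking", "single_discrimination", "dual")) {
    if (!any(trials$condition == cond)) {
      stop("no trials for condition '", cond, "'", call. = FALSE)
    }
  }
  cond_mean <- function(cond, col) {
    v <- trials[[col]][trials$condition == cond]
    mean(v[!is.na(v)])
  }
  single_tracking <- cond_mean("single_tracking", "tracking_accuracy")
  dual_tracking <- cond_mean("dual", "tracking_accuracy")
  single_discrim <- cond_mean("single_discrimination", "discrimination_accuracy")
  dual_discrim <- cond_mean("dual", "discrimination_accuracy")
  single_rt <- cond_mean("single_discrimination", "mean_rt")
  dual_rt <- cond_mean("dual", "mean_rt")
  tibble::tibble(
    single_tracking = single_tracking, dual_tracking = dual_tracking,
    single_discrim = single_discrim, dual_discrim = dual_discrim,
    single_rt = single_rt, dual_rt = dual_rt,
    tracking_cost = single_tracking - dual_tracking,
    discrim_cost = single_discrim - dual_discrim,
    rt_cost = dual_rt - single_rt,
    overall_cost = (single_tracking - dual_tracking) +
      (single_discrim - dual_discrim))
}

#' Cost summaries for every participant and test session in a cohort
#'
#' @param trials A cohort trial table (e.g. `run_cohort()$trials`).
#' @return A tibble with one row per participant and session (`pre`,
#'   `post`), carrying `group` and all [compute_costs()] columns.
#' @export
cohort_costs <- function(trials) {
  test <- trials[trials$phase %in% c("pre", "post"), ]
  if (nrow(test) == 0) stop("no pre/post test trials found", call. = FALSE)
  present <- test |>
    dplyr::distinct(.data$participant_id, .data$phase, .data$condition) |>
    dplyr::count(.data$participant_id, .data$phase)
  if (any(present$n < 3)) {
    bad <- present[present$n < 3, ]
    stop("missing test condition(s) for participant ",
         paste(unique(bad$participant_id), collapse = ", "), call. = FALSE)
  }
  # grouped vectorization of compute_costs(); the suite asserts agreement
  out <- test |>
    dplyr::group_by(.data$participant_id, .data$group, .data$phase) |>
    dplyr::summarise(
      single_tracking = mean(.data$tracking_accuracy[
        .data$condition == "single_tracking"], na.rm = TRUE),
      dual_tracking = mean(.data$tracking_accuracy[
        .data$condition == "dual"], na.rm = TRUE),
      single_discrim = mean(.data$discrimination_accuracy[
        .data$condition == "single_discrimination"], na.rm = TRUE),
      dual_discrim = mean(.data$discrimination_accuracy[
        .data$condition == "dual"], na.rm = TRUE),
      single_rt = mean(.data$mean_rt[
        .data$condition == "single_discrimination"], na.rm = TRUE),
      dual_rt = mean(.data$mean_rt[.data$condition == "dual"], na.rm = TRUE),
      .groups = "drop") |>
    dplyr::mutate(
      tracking_cost = .data$single_tracking - .data$dual_tracking,
      discrim_cost = .data$single_discrim - .data$dual_discrim,
      rt_cost = .data$dual_rt - .data$single_rt,
      overall_cost = .data$tracking_cost + .data$discrim_cost) |>
    dplyr::rename(session = "phase")
  out$session <- factor(out$session, levels = c("pre", "post"))
  out
}

#' Psychological refractory period effect
#'
#' Mean correct task-2 RT at the 200 ms SOA minus the mean at the 1000 ms
#' SOA.
#'
#' @param trials PRP trial table with columns `soa`, `rt2`, `correct2`.
#' @return Effect in ms.
#' @export
prp_effect <- function(trials) {
  ok <- trials$correct2
  short <- trials$rt2[ok & trials$soa == 200]
  long <- trials$rt2[ok & trials$soa == 1000]
  if (!length(short) || !length(long)) {
    stop("no correct task-2 responses at one of the SOAs", call. = FALSE)
  }
  mean(short) - mean(long)
}

#' Attentional blink magnitude
#'
#' T2 accuracy is scored only on trials where T1 was reported correctly
#' (T2|T1). The magnitude is the mean of lags 5 and 7 minus the mean of
#' lags 2 and 3, in percentage points.
#'
#' @param trials AB trial table with columns `lag`, `t1_correct`,
#'   `t2_correct`.
#' @return Magnitude in percentage points.
#' @export
ab_magnitude <- function(trials) {
  acc <- vapply(c(2, 3, 5, 7), function(l) {
    sel <- trials$lag == l & trials$t1_correct
    if (!any(sel)) {
      stop("no T1-correct trials at lag ", l, call. = FALSE)
    }
    100 * mean(trials$t2_correct[sel])
  }, numeric(1))
  mean(acc[3:4]) - mean(acc[1:2])
}

#' Stroop / flanker congruency effect
#'
#' Mean correct RT on incongruent trials minus congruent trials; neutral
#' trials are excluded from the contrast.
#'
#' @param trials Trial table with columns `trial_type`, `rt`, `correct`.
#' @param task `"stroop"` or `"flanker"` (scoring is identical; the label
#'   is kept for validation and reporting).
#' @return Effect in ms.
#' @export
congruency_effect <- function(trials, task = c("stroop", "flanker")) {
  task <- match.arg(task)
  ok <- trials$correct
  inc <- trials$rt[ok & trials$trial_type == "incongruent"]
  con <- trials$rt[ok & trials$trial_type == "congruent"]
  if (!length(inc) || !length(con)) {
    stop("no correct trials in one of the congruency conditions",
         call. = FALSE)
  }
  mean(inc) - mean(con)
}

#' Go/no-go statistics
#'
#' @param trials Go/no-go trial table with columns `go`, `responded`, `rt`.
#' @return A list with `commission_rate` (% of no-go trials with a
#'   response) and `go_rt` (mean RT on responded go trials, ms).
#' @export
gonogo_stats <- function(trials) {
  nogo <- !trials$go
  if (!any(nogo)) stop("no no-go trials", call. = FALSE)
  go_rts <- trials$rt[trials$go & trials$responded]
  list(commission_rate = 100 * mean(trials$responded[nogo]),
       go_rt = if (length(go_rts)) mean(go_rts) else NA_real_)
}

#' Transfer-effect summaries for a cohort
#'
#' Computes every transfer task's key dependent measure per participant and
#' session from the trial tables.
#'
#' @param transfer Named list of long per-task tables
#'   (`run_cohort()$transfer`).
#' @return A tibble with one row per participant and session: `prp_effect`,
#'   `single_rs_rt`, `stroop_effect`, `ab_magnitude`, `flanker_effect`,
#'   `commission_rate`, `go_rt`.
#' @export
transfer_summary <- function(transfer) {
  needed <- c("prp", "single_rs", "stroop", "ab", "gonogo", "flanker")
  stopifnot(all(needed %in% names(transfer)))
  by_ps <- function(tab) {
    dplyr::group_by(tab, .data$participant_id, .data$group, .data$session)
  }
  # vectorized grouped versions of the per-participant statistics; each
  # agrees with its scalar counterpart (prp_effect() etc.), which the test
  # suite asserts
  prp <- by_ps(transfer$prp) |>
    dplyr::summarise(prp_effect = mean(.data$rt2[.data$correct2 & .data$soa == 200]) -
                       mean(.data$rt2[.data$correct2 & .data$soa == 1000]),
                     .groups = "drop")
  rs <- by_ps(transfer$single_rs) |>
    dplyr::summarise(single_rs_rt = mean(.data$rt[.data$correct]),
                     .groups = "drop")
  cong <- function(tab, out_name) {
    out <- by_ps(tab) |>
      dplyr::summarise(
        effect = mean(.data$rt[.data$correct &
                                 .data$trial_type == "incongruent"]) -
          mean(.data$rt[.data$correct & .data$trial_type == "congruent"]),
        .groups = "drop")
    names(out)[names(out) == "effect"] <- out_name
    out
  }
  stroop <- cong(transfer$stroop, "stroop_effect")
  flk <- cong(transfer$flanker, "flanker_effect")
  ab <- by_ps(transfer$ab) |>
    dplyr::summarise(
      ab_magnitude = 100 *
        ((mean(.data$t2_correct[.data$t1_correct & .data$lag == 5]) +
            mean(.data$t2_correct[.data$t1_correct & .data$lag == 7])) / 2 -
           (mean(.data$t2_correct[.data$t1_correct & .data$lag == 2]) +
              mean(.data$t2_correct[.data$t1_correct & .data$lag == 3])) / 2),
      .groups = "drop")
  gng <- by_ps(transfer$gonogo) |>
    dplyr::summarise(commission_rate = 100 * mean(.data$responded[!.data$go]),
                     go_rt = mean(.data$rt[.data$go & .data$responded]),
                     .groups = "drop")
  out <- Reduce(function(a, b) {
    dplyr::left_join(a, b, by = c("participant_id", "group", "session"))
  }, list(prp, rs, stroop, ab, gng, flk))
  out$session <- factor(out$session, levels = c("pre", "post"))
  out
}

#' Apply the a-priori outlier exclusion rule
#'
#' Excludes any participant whose pre-training mean RT on any of the six
#' transfer tasks exceeds the cohort mean by more than 3 SD, or whose
#' pre-training accuracy on any task falls more than 3 SD below the cohort
#' mean. Cohort means and SDs are computed per task over the full enrolled
#' cohort in a single pass (no iteration after removals). Protocol
#' non-completers can be excluded via `completed`.
#'
#' @param transfer Named list of long per-task transfer tables (pre and
#'   post sessions; only `session == "pre"` is used for the rule).
#' @param completed Optional character vector of participant ids that
#'   completed all sessions; ids absent from it are excluded as
#'   non-completers.
#' @param n_sd SD multiplier (3, fixed a priori).
#' @return A list with `retained` (character vector) and `excluded` (tibble
#'   of `participant_id`, `reason`).
#' @export
apply_exclusions <- function(transfer, completed = NULL, n_sd = 3) {
  stats_tbl <- exclusion_summary(transfer)
  ids <- unique(stats_tbl$participant_id)
  if (length(ids) < 3) {
    stop("cohort too small for SD-based exclusion (need >= 3)", call. = FALSE)
  }
  flagged <- stats_tbl |>
    dplyr::group_by(.data$task) |>
    dplyr::mutate(
      rt_out = !is.na(.data$mean_rt) &
        .data$mean_rt > mean(.data$mean_rt, na.rm = TRUE) +
        n_sd * stats::sd(.data$mean_rt, na.rm = TRUE),
      acc_out = !is.na(.data$accuracy) &
        .data$accuracy < mean(.data$accuracy, na.rm = TRUE) -
        n_sd * stats::sd(.data$accuracy, na.rm = TRUE)) |>
    dplyr::ungroup()
  excluded <- flagged |>
    dplyr::filter(.data$rt_out | .data$acc_out) |>
    dplyr::mutate(reason = paste0(
      ifelse(.data$rt_out, "slow RT", "low accuracy"), " on ", .data$task)) |>
    dplyr::select("participant_id", "reason")
  if (!is.null(completed)) {
    nc <- setdiff(ids, completed)
    if (length(nc)) {
      excluded <- dplyr::bind_rows(
        excluded, tibble::tibble(participant_id = nc,
                                 reason = "did not complete all sessions"))
    }
  }
  excluded <- dplyr::distinct(dplyr::arrange(excluded, .data$participant_id))
  list(retained = setdiff(ids, excluded$participant_id), excluded = excluded)
}

# Per-participant, per-task pre-training RT and accuracy summaries used by
# the exclusion rule. The AB task has no speeded response, so only its
# accuracy enters; go/no-go accuracy is the non-commission rate.
exclusion_summary <- function(transfer) {
  needed <- c("prp", "single_rs", "stroop", "ab", "gonogo", "flanker")
  stopifnot(all(needed %in% names(transfer)))
  pre <- lapply(transfer, function(t) t[t$session == "pre", ])
  one <- function(tab, task, f) {
    tab |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::group_modify(~ tibble::as_tibble(f(.x))) |>
      dplyr::ungroup() |>
      dplyr::mutate(task = task)
  }
  dplyr::bind_rows(
    one(pre$prp, "prp", function(d) {
      list(mean_rt = mean(d$rt2[d$correct2]), accuracy = 100 * mean(d$correct2))
    }),
    one(pre$single_rs, "single_rs", function(d) {
      list(mean_rt = mean(d$rt[d$correct]), accuracy = 100 * mean(d$correct))
    }),
    one(pre$stroop, "stroop", function(d) {
      list(mean_rt = mean(d$rt[d$correct]), accuracy = 100 * mean(d$correct))
    }),
    one(pre$ab, "ab", function(d) {
      list(mean_rt = NA_real_,
           accuracy = 100 * mean(d$t2_correct[d$t1_correct]))
    }),
    one(pre$gonogo, "gonogo", function(d) {
      s <- gonogo_stats(d)
      list(mean_rt = s$go_rt, accuracy = 100 - s$commission_rate)
    }),
    one(pre$flanker, "flanker", function(d) {
      list(mean_rt = mean(d$rt[d$correct]), accuracy = 100 * mean(d$correct))
    }))
}
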