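#' Protocol configuration
#'
#' The ten-session experimental schedule for each simulated participant:
#' adaptive thresholding (nine 60 s tracking trials, nine 120 s
#' discrimination trials), a pre-test of five 3-minute trials per condition
#' (single tracking, single discrimination, dual), six training sessions of
#' twelve 3-minute trials (all dual for the multitask group; six of each
#' single task, order randomized per participant, for the single-task
#' group), a structurally identical post-test, and the pre/post transfer
#' battery. Difficulty levels chosen at thresholding stay fixed for the
#' remainder of the experiment.
#'
#' Bonus points: multitask-group trials earn +1 when both component
#' accuracies exceed 70%, single-task trials earn +1 when the scored
#' accuracy exceeds 85%; otherwise the trial loses a point.
#'
#' @param staircase A [staircase_config()].
#' @param n_test_trials Test trials per condition per session.
#' @param test_duration,training_duration Trial lengths (s).
#' @param n_training_sessions,trials_per_training_session Training layout.
#' @param thresh_duration_tracking,thresh_duration_discrim Thresholding
#'   trial lengths (s).
#' @param bonus_dual_criterion,bonus_single_criterion Accuracy cut-offs (%).
#' @param include_training Simulate training trials? Learning in the
#'   observer model is driven by session counts, not trial outcomes, so
#'   replicate studies may switch the (causally inert) training trials off.
#' @param include_transfer Simulate the transfer battery?
#' @return A `protocol_config` list.
#' @export
protocol_config <- function(staircase = staircase_config(),
                            n_test_trials = 5L, test_duration = 180,
                            n_training_sessions = 6L,
                            trials_per_training_session = 12L,
                            training_duration = 180,
                            thresh_duration_tracking = 60,
                            thresh_duration_discrim = 120,
                            bonus_dual_criterion = 70,
                            bonus_single_criterion = 85,
                            include_training = TRUE,
                            include_transfer = TRUE) {
  stopifnot(inherits(staircase, "staircase_config"),
            n_test_trials >= 1, test_duration > 0,
            n_training_sessions >= 0, trials_per_training_session >= 2,
            trials_per_training_session %% 2 == 0,
            thresh_duration_tracking > 0, thresh_duration_discrim > 0)
  structure(
    list(staircase = staircase,
         n_test_trials = as.integer(n_test_trials),
         test_duration = test_duration,
         n_training_sessions = as.integer(n_training_sessions),
         trials_per_training_session = as.integer(trials_per_training_session),
         training_duration = training_duration,
         thresh_duration_tracking = thresh_duration_tracking,
         thresh_duration_discrim = thresh_duration_discrim,
         bonus_dual_criterion = bonus_dual_criterion,
         bonus_single_criterion = bonus_single_criterion,
         include_training = include_training,
         include_transfer = include_transfer),
    class = "protocol_config"
  )
}

#' Award the bonus point for a training trial
#'
#' @param record A training-trial record (list or one-row data frame with
#'   `phase`, `condition`, and the scored accuracies).
#' @param group `"multitask"` or `"single"`.
#' @param dual_criterion,single_criterion Accuracy cut-offs (%).
#' @return `+1L` or `-1L`.
#' @export
#' @examples
#' award_bonus(list(phase = "train", condition = "dual",
#'                  tracking_accuracy = 75, discrimination_accuracy = 72),
#'             "multitask")  # +1
award_bonus <- function(record, group = c("multitask", "single"),
                        dual_criterion = 70, single_criterion = 85) {
  group <- match.arg(group)
  if (is.data.frame(record)) record <- as.list(record)
  if (is.null(record$phase) || record$phase != "train") {
    stop("bonus points are only awarded on training trials", call. = FALSE)
  }
  if (group == "multitask") {
    if (record$condition != "dual") {
      stop("multitask-group training trials must be dual", call. = FALSE)
    }
    ok <- record$tracking_accuracy > dual_criterion &&
      record$discrimination_accuracy > dual_criterion
  } else {
    acc <- switch(record$condition,
                  single_tracking = record$tracking_accuracy,
                  single_discrimination = record$discrimination_accuracy,
                  stop("single-group training trials must be single-task",
                       call. = FALSE))
    ok <- acc > single_criterion
  }
  if (ok) 1L else -1L
}

# Column-wise conversion of a list of identically named trial rows.
rows_to_tibble <- function(rows) {
  nm <- names(rows[[1]])
  cols <- lapply(nm, function(k) {
    unlist(lapply(rows, `[[`, k), use.names = FALSE)
  })
  names(cols) <- nm
  tibble::as_tibble(cols)
}

trial_row <- function(observer, phase, session_index, trial_index, rec,
                      tracking_level, discrim_level) {
  list(participant_id = observer$id, group = observer$group, phase = phase,
       session_index = as.integer(session_index),
       trial_index = as.integer(trial_index),
       condition = rec$condition, duration = rec$duration,
       tracking_level = as.integer(tracking_level),
       discrim_level = as.integer(discrim_level),
       tracking_accuracy = rec$tracking_accuracy,
       discrimination_accuracy = rec$discrimination_accuracy,
       mean_rt = rec$mean_rt)
}

#' Run one participant through the full protocol
#'
#' Thresholds both component tasks, fixes the chosen difficulty levels,
#' then runs pre-test, training (with group-specific composition, bonus
#' points, and per-session learning), post-test, and the pre/post transfer
#' battery. All randomness is drawn from named sub-streams of the master
#' seed, so one participant's results do not depend on another's.
#'
#' @param observer An [observer_params()].
#' @param protocol A [protocol_config()].
#' @param effects A [transfer_effect_params()] (used when
#'   `include_transfer`).
#' @param seed Master integer seed (the cohort's).
#' @return A run ledger: list with `trials` (tibble of trial records),
#'   `levels` (chosen tracking/discrimination levels), `bonus_points`
#'   (tally), `session_feedback` (per training session summary), and
#'   `transfer` (list of `pre`/`post` table sets, or `NULL`).
#' @export
run_participant <- function(observer, protocol = protocol_config(),
                            effects = transfer_effect_params(), seed = 1L) {
  stopifnot(inherits(observer, "observer_params"),
            inherits(protocol, "protocol_config"))
  scfg <- protocol$staircase
  track_ladder <- build_ladder("tracking_speed")
  rt_ladder <- build_ladder("rt_window")
  rows <- vector("list", 256); n_rows <- 0L
  push <- function(row) {
    n_rows <<- n_rows + 1L
    if (n_rows > length(rows)) length(rows) <<- 2L * n_rows
    rows[[n_rows]] <<- row
  }

  # -- thresholding ---------------------------------------------------------
  track_runner <- function(obs, value, duration) {
    run_trial_core(obs, "single_tracking", tracking_params(value), NULL,
                   duration)$tracking_accuracy
  }
  disc_runner <- function(obs, value, duration) {
    run_trial_core(obs, "single_discrimination", NULL,
                   discrimination_params(value),
                   duration)$discrimination_accuracy
  }
  th_track <- run_threshold_phase(
    observer, track_ladder, scfg, track_runner,
    protocol$thresh_duration_tracking,
    seed = derive_seed(seed, paste0(observer$id, "/threshold/tracking")))
  th_disc <- run_threshold_phase(
    observer, rt_ladder, scfg, disc_runner,
    protocol$thresh_duration_discrim,
    seed = derive_seed(seed, paste0(observer$id, "/threshold/discrim")))
  for (i in seq_len(nrow(th_track$history))) {
    push(trial_row(observer, "threshold", 0L, i,
                   list(condition = "single_tracking",
                        duration = protocol$thresh_duration_tracking,
                        tracking_accuracy = th_track$history$accuracy[i],
                        discrimination_accuracy = NA_real_,
                        mean_rt = NA_real_),
                   th_track$history$level[i], NA_integer_))
  }
  for (i in seq_len(nrow(th_disc$history))) {
    push(trial_row(observer, "threshold", 0L, nrow(th_track$history) + i,
                   list(condition = "single_discrimination",
                        duration = protocol$thresh_duration_discrim,
                        tracking_accuracy = NA_real_,
                        discrimination_accuracy = th_disc$history$accuracy[i],
                        mean_rt = NA_real_),
                   NA_integer_, th_disc$history$level[i]))
  }
  levels <- c(tracking = th_track$chosen_level, discrim = th_disc$chosen_level)
  tracking <- tracking_params(ladder_value(track_ladder, levels["tracking"]))
  discrimination <- discrimination_params(ladder_value(rt_ladder,
                                                       levels["discrim"]))
  multitask <- observer$group == "multitask"

  run_test_block <- function(phase, session_index, sessions, dual_sessions) {
    set.seed(derive_seed(seed, paste0(observer$id, "/", phase, "-test")))
    k <- 0L
    for (cond in c("single_tracking", "single_discrimination", "dual")) {
      for (i in seq_len(protocol$n_test_trials)) {
        rec <- run_trial_core(observer, cond, tracking, discrimination,
                              protocol$test_duration, sessions, dual_sessions)
        k <- k + 1L
        push(trial_row(observer, phase, session_index, k, rec,
                       levels["tracking"], levels["discrim"]))
      }
    }
  }

  # -- pre-test -------------------------------------------------------------
  run_test_block("pre", 0L, 0, 0)

  # -- training -------------------------------------------------------------
  bonus <- 0L
  feedback <- NULL
  if (protocol$include_training && protocol$n_training_sessions > 0) {
    half <- protocol$trials_per_training_session / 2
    set.seed(derive_seed(seed, paste0(observer$id, "/training-order")))
    single_order <- sample(rep(c("single_tracking", "single_discrimination"),
                               each = half))
    fb <- vector("list", protocol$n_training_sessions)
    for (s in seq_len(protocol$n_training_sessions)) {
      set.seed(derive_seed(seed, paste0(observer$id, "/train/", s)))
      conds <- if (multitask) {
        rep("dual", protocol$trials_per_training_session)
      } else {
        single_order
      }
      s_track <- c(); s_disc <- c(); s_bonus <- 0L
      for (i in seq_along(conds)) {
        rec <- run_trial_core(observer, conds[i], tracking, discrimination,
                              protocol$training_duration,
                              sessions_completed = s - 1,
                              dual_sessions_completed = if (multitask) s - 1 else 0)
        row <- trial_row(observer, "train", s, i, rec,
                         levels["tracking"], levels["discrim"])
        push(row)
        b <- award_bonus(row, observer$group,
                         protocol$bonus_dual_criterion,
                         protocol$bonus_single_criterion)
        bonus <- bonus + b; s_bonus <- s_bonus + b
        if (!is.na(rec$tracking_accuracy)) s_track <- c(s_track, rec$tracking_accuracy)
        if (!is.na(rec$discrimination_accuracy)) s_disc <- c(s_disc, rec$discrimination_accuracy)
      }
      fb[[s]] <- list(session = s,
                      mean_tracking = if (length(s_track)) mean(s_track) else NA_real_,
                      mean_discrimination = if (length(s_disc)) mean(s_disc) else NA_real_,
                      bonus = s_bonus)
    }
    feedback <- rows_to_tibble(fb)
  }

  # -- post-test ------------------------------------------------------------
  n_sessions <- protocol$n_training_sessions
  run_test_block("post", n_sessions + 1L, n_sessions,
                 if (multitask) n_sessions else 0)

  # -- transfer battery -----------------------------------------------------
  transfer <- NULL
  if (protocol$include_transfer) {
    if (is.null(observer$transfer)) {
      # observer built by hand rather than sampled: draw its personal
      # transfer profile from a dedicated sub-stream
      set.seed(derive_seed(seed, paste0(observer$id, "/transfer-profile")))
      observer$transfer <- sample_transfer_profile(effects)
    }
    transfer <- list(
      pre = generate_transfer_tables(
        observer, effects, "pre",
        seed = derive_seed(seed, paste0(observer$id, "/transfer/pre"))),
      post = generate_transfer_tables(
        observer, effects, "post",
        seed = derive_seed(seed, paste0(observer$id, "/transfer/post"))))
  }

  list(trials = rows_to_tibble(rows[seq_len(n_rows)]),
       levels = levels, bonus_points = bonus,
       session_feedback = feedback, transfer = transfer)
}

#' Run a full cohort
#'
#' Samples (or accepts) a population of observers and runs each through the
#' protocol, concatenating all ledgers into one tidy dataset.
#'
#' @param population A [population_config()] (sampled from a sub-stream of
#'   `seed`) or a pre-sampled list of [observer_params()].
#' @param protocol A [protocol_config()].
#' @param effects A [transfer_effect_params()]; defaults to the population
#'   config's transfer parameters when available.
#' @param seed Master integer seed.
#' @return A `dts_cohort` list: `trials` (all trial records), `transfer`
#'   (named list of per-task long tables, or `NULL`), `participants`
#'   (id, group, chosen levels, bonus tally), and `seed`.
#' @export
run_cohort <- function(population = population_config(),
                       protocol = protocol_config(), effects = NULL,
                       seed = 1L) {
  if (inherits(population, "population_config")) {
    effects <- effects %||% population$transfer
    observers <- sample_population(population,
                                   seed = derive_seed(seed, "population"))
  } else {
    stopifnot(is.list(population),
              all(vapply(population, inherits, TRUE, "observer_params")))
    effects <- effects %||% transfer_effect_params()
    observers <- population
  }
  ledgers <- lapply(observers, run_participant, protocol = protocol,
                    effects = effects, seed = seed)
  trials <- dplyr::bind_rows(lapply(ledgers, `[[`, "trials"))
  transfer <- NULL
  if (protocol$include_transfer) {
    tasks <- names(ledgers[[1]]$transfer$pre)
    transfer <- lapply(tasks, function(task) {
      dplyr::bind_rows(lapply(ledgers, function(l) {
        dplyr::bind_rows(l$transfer$pre[[task]], l$transfer$post[[task]])
      }))
    })
    names(transfer) <- tasks
  }
  participants <- tibble::tibble(
    participant_id = vapply(observers, `[[`, "", "id"),
    group = vapply(observers, `[[`, "", "group"),
    tracking_level = vapply(ledgers, function(l) unname(l$levels["tracking"]), 1L),
    discrim_level = vapply(ledgers, function(l) unname(l$levels["discrim"]), 1L),
    bonus_points = vapply(ledgers, `[[`, 1L, "bonus_points"))
  structure(list(trials = trials, transfer = transfer,
                 participants = participants, seed = seed),
            class = "dts_cohort")
}
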