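#' Staircase configuration
#'
#' Parameters of the adaptive thresholding procedure. After every
#' thresholding trial the accuracy is compared with the 80% criterion: inside
#' the 77.5--82.5% deadband the difficulty level is left alone; outside it the
#' level moves proportionally, one level per 1.75 accuracy points away from
#' the criterion. Nine trials are run starting from level 29, and the test
#' level is then chosen by an ordinary-least-squares regression of level on
#' accuracy, evaluated at the criterion.
#'
#' @param criterion Target accuracy, percent.
#' @param deadband_low,deadband_high Accuracy band (percent) within which the
#'   level is not changed.
#' @param gain Accuracy points per level step.
#' @param start_level Initial ladder level.
#' @param n_threshold_trials Number of thresholding trials.
#' @return A `staircase_config` list.
#' @export
staircase_config <- function(criterion = 80, deadband_low = 77.5,
                             deadband_high = 82.5, gain = 1.75,
                             start_level = 29L, n_threshold_trials = 9L) {
  stopifnot(deadband_low < criterion, criterion < deadband_high,
            gain > 0, start_level >= 1, start_level <= 49,
            n_threshold_trials >= 2)
  structure(
    list(criterion = criterion, deadband_low = deadband_low,
         deadband_high = deadband_high, gain = gain,
         start_level = as.integer(start_level),
         n_threshold_trials = as.integer(n_threshold_trials)),
    class = "staircase_config"
  )
}

#' Initialise staircase state
#'
#' @param ladder A [build_ladder()] ladder.
#' @param cfg A [staircase_config()].
#' @return A `staircase_state` list with the current level and an empty
#'   `(level, accuracy)` history.
#' @export
staircase_state <- function(ladder, cfg = staircase_config()) {
  stopifnot(inherits(ladder, "difficulty_ladder"),
            inherits(cfg, "staircase_config"))
  structure(
    list(ladder = ladder, cfg = cfg,
         current_level = cfg$start_level,
         history_level = integer(), history_accuracy = double()),
    class = "staircase_state"
  )
}

#' @rdname staircase_state
#' @param state A `staircase_state`.
#' @return `staircase_history()` returns the recorded `(level, accuracy)`
#'   pairs as a tibble, in trial order.
#' @export
staircase_history <- function(state) {
  stopifnot(inherits(state, "staircase_state"))
  tibble::tibble(level = state$history_level,
                 accuracy = state$history_accuracy)
}

#' Apply one proportional staircase update
#'
#' Records `(current level, accuracy)` in the history, then moves the level
#' by `round((accuracy - criterion) / gain)` levels (round half away from
#' zero), clamped to 1..49, unless the accuracy falls inside the deadband, in
#' which case the level is unchanged.
#'
#' @param state A `staircase_state`.
#' @param accuracy Observed trial accuracy in percent, 0..100.
#' @return The updated `staircase_state`.
#' @export
#' @examples
#' st <- staircase_state(build_ladder("tracking_speed"))
#' update_level(st, 86)$current_level  # 29 + round(6 / 1.75) = 32
update_level <- function(state, accuracy) {
  stopifnot(inherits(state, "staircase_state"))
  if (!is.numeric(accuracy) || length(accuracy) != 1 ||
      is.na(accuracy) || accuracy < 0 || accuracy > 100) {
    stop("accuracy must be a single value in [0, 100]", call. = FALSE)
  }
  cfg <- state$cfg
  if (length(state$history_level) >= cfg$n_threshold_trials) {
    stop("staircase history already holds n_threshold_trials entries",
         call. = FALSE)
  }
  state$history_level <- c(state$history_level, state$current_level)
  state$history_accuracy <- c(state$history_accuracy, accuracy)
  if (accuracy < cfg$deadband_low || accuracy > cfg$deadband_high) {
    delta <- round_half_away((accuracy - cfg$criterion) / cfg$gain)
    state$current_level <-
      as.integer(clamp(state$current_level + delta, 1L, 49L))
  }
  state
}

# Unrounded OLS prediction of the level giving `target` accuracy, from the
# normal equations: slope = cov(acc, level) / var(acc). Kept separate so
# the rounding rule can be tested against stats::lm independently.
ols_level_at <- function(history, target) {
  acc <- history$accuracy
  lvl <- history$level
  slope <- stats::cov(acc, lvl) / stats::var(acc)
  intercept <- mean(lvl) - slope * mean(acc)
  intercept + slope * target
}

#' Select the test level from a thresholding history
#'
#' Fits level as an ordinary-least-squares function of accuracy over the
#' `(level, accuracy)` history and returns the rounded level predicted at the
#' target accuracy, clamped to 1..49. If every recorded accuracy is
#' identical the regressor has zero variance; the most recent level is then
#' returned with a warning.
#'
#' @param history A data frame with columns `level` and `accuracy` (at least
#'   two rows).
#' @param target Accuracy (percent) at which to read off the level.
#' @return An integer level in 1..49.
#' @export
#' @examples
#' fit_threshold(data.frame(level = c(10, 20, 30), accuracy = c(90, 80, 70)))
fit_threshold <- function(history, target = 80) {
  stopifnot(is.data.frame(history), nrow(history) >= 2,
            all(c("level", "accuracy") %in% names(history)))
  if (stats::var(history$accuracy) == 0) {
    warning("all thresholding accuracies identical; returning last level",
            call. = FALSE)
    return(as.integer(history$level[nrow(history)]))
  }
  as.integer(clamp(round_half_away(ols_level_at(history, target)), 1L, 49L))
}

#' Run the full thresholding phase for one observer
#'
#' Runs `n_threshold_trials` trials starting from the configured start level,
#' applying [update_level()] after each trial, then selects the test level
#' with [fit_threshold()] over the accumulated history.
#'
#' @param observer Passed through to `trial_runner`.
#' @param ladder A [build_ladder()] ladder.
#' @param cfg A [staircase_config()].
#' @param trial_runner `function(observer, difficulty_value, duration)`
#'   returning a trial accuracy in percent.
#' @param duration Trial duration (s) handed to `trial_runner`.
#' @param seed Optional integer seed for the phase.
#' @return A list with `chosen_level` (integer), `state` (the final
#'   `staircase_state`), and `history` (tibble of all `(level, accuracy)`
#'   pairs in trial order).
#' @export
run_threshold_phase <- function(observer, ladder, cfg, trial_runner,
                                duration, seed = NULL) {
  stopifnot(is.function(trial_runner), duration > 0)
  if (!is.null(seed)) set.seed(seed)
  state <- staircase_state(ladder, cfg)
  for (i in seq_len(cfg$n_threshold_trials)) {
    value <- ladder_value(ladder, state$current_level)
    acc <- trial_runner(observer, value, duration)
    state <- update_level(state, acc)
  }
  history <- staircase_history(state)
  chosen <- withCallingHandlers(
    fit_threshold(history, cfg$criterion),
    warning = function(w) invokeRestart("muffleWarning")
  )
  list(chosen_level = chosen, state = state, history = history)
}
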