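#' Construct a synthetic observer
#'
#' A synthetic participant is described by logistic psychometric functions
#' for the two component tasks, a shifted log-normal response-time
#' distribution, dual-task interference parameters, and linear per-session
#' learning rates. The psychometric functions are anchored at the 80% point:
#' at `track_midpoint` dps (or `discrim_midpoint` ms) the expected single-task
#' accuracy is exactly 80%, the thresholding criterion.
#'
#' Interference is expressed in accuracy percentage points lost under dual
#' conditions at the observer's operating level. Single-task learning moves
#' the psychometric midpoints (dps / ms per completed training session, both
#' groups); dual-task coordination learning reduces the interference
#' parameter, and accrues only over sessions in which the two tasks were
#' trained in combination.
#'
#' @param id Participant identifier.
#' @param group `"multitask"` or `"single"`.
#' @param track_midpoint Target speed (dps) at which tracking accuracy is 80%.
#' @param track_slope Logistic slope for tracking (per dps).
#' @param discrim_midpoint Response window (ms) at which discrimination
#'   accuracy is 80%.
#' @param discrim_slope Logistic slope for discrimination (per ms).
#' @param lapse Lapse probability in `[0, 0.05]`; bounds the upper asymptote
#'   at `100 * (1 - lapse)`.
#' @param rt_shift,rt_meanlog,rt_sdlog Shifted log-normal response-time
#'   parameters (ms): `rt = rt_shift + rlnorm(rt_meanlog, rt_sdlog)`,
#'   truncated at the response window.
#' @param rt_interference Added to `rt_shift` (ms) under dual conditions.
#' @param false_alarm_rate Per-distractor response probability.
#' @param interference_track,interference_discrim Dual-task accuracy costs in
#'   percentage points (non-negative).
#' @param learning_track,learning_discrim Midpoint improvement per completed
#'   training session (dps, ms).
#' @param learning_rate_dual Interference reduction (points) per completed
#'   dual-training session.
#' @param transfer Named list of personal transfer-task baselines (see
#'   [transfer_effect_params()]); may be `NULL` if the transfer battery is
#'   not simulated.
#' @return An `observer_params` list.
#' @export
observer_params <- function(id = "p01", group = c("multitask", "single"),
                            track_midpoint = 0.092, track_slope = 130,
                            discrim_midpoint = 450, discrim_slope = 0.013,
                            lapse = 0.01,
                            rt_shift = 100, rt_meanlog = log(220),
                            rt_sdlog = 0.25, rt_interference = 13,
                            false_alarm_rate = 0.05,
                            interference_track = 0,
                            interference_discrim = 15.6,
                            learning_track = 0.00055,
                            learning_discrim = 4.2,
                            learning_rate_dual = 1.2,
                            transfer = NULL) {
  group <- match.arg(group)
  stopifnot(track_slope > 0, discrim_slope > 0,
            lapse >= 0, lapse <= 0.05,
            interference_track >= 0, interference_discrim >= 0,
            false_alarm_rate >= 0, false_alarm_rate <= 1,
            rt_sdlog >= 0, rt_shift >= 0)
  structure(
    list(id = id, group = group,
         track_midpoint = track_midpoint, track_slope = track_slope,
         discrim_midpoint = discrim_midpoint, discrim_slope = discrim_slope,
         lapse = lapse, rt_shift = rt_shift, rt_meanlog = rt_meanlog,
         rt_sdlog = rt_sdlog, rt_interference = rt_interference,
         false_alarm_rate = false_alarm_rate,
         interference_track = interference_track,
         interference_discrim = interference_discrim,
         learning_track = learning_track,
         learning_discrim = learning_discrim,
         learning_rate_dual = learning_rate_dual,
         transfer = transfer),
    class = "observer_params"
  )
}

#' Expected accuracy from an observer's psychometric function
#'
#' Evaluates the lapse-bounded logistic psychometric function at a difficulty
#' value. Tracking accuracy decreases with target speed; discrimination
#' accuracy increases with the response window. Under `dual = TRUE` the
#' session-dependent interference (percentage points, reduced by
#' `learning_rate_dual` per completed dual-training session) is subtracted
#' at the operating level and the result clamped to `[0, 100]`.
#'
#' @param observer An [observer_params()].
#' @param task `"tracking"` or `"discrimination"`.
#' @param difficulty Difficulty value (dps or ms).
#' @param dual Whether the task is performed concurrently with the other.
#' @param sessions_completed Completed training sessions (single-skill
#'   learning, both groups).
#' @param dual_sessions_completed Completed dual-training sessions
#'   (coordination learning; 0 for the single-task group throughout).
#' @return Expected accuracy in percent.
#' @export
#' @examples
#' ob <- observer_params()
#' psychometric_accuracy(ob, "tracking", ob$track_midpoint)          # 80
#' psychometric_accuracy(ob, "discrimination", 450, dual = TRUE)     # ~64.4
psychometric_accuracy <- function(observer,
                                  task = c("tracking", "discrimination"),
                                  difficulty, dual = FALSE,
                                  sessions_completed = 0,
                                  dual_sessions_completed = 0) {
  task <- match.arg(task)
  asym <- 100 * (1 - observer$lapse)
  b <- stats::qlogis(80 / asym)
  if (task == "tracking") {
    m <- observer$track_midpoint +
      observer$learning_track * sessions_completed
    acc <- asym * stats::plogis(b + observer$track_slope * (m - difficulty))
    interference <- observer$interference_track
  } else {
    m <- observer$discrim_midpoint -
      observer$learning_discrim * sessions_completed
    acc <- asym * stats::plogis(b + observer$discrim_slope * (difficulty - m))
    interference <- observer$interference_discrim
  }
  if (dual) {
    eff <- max(0, interference -
                 observer$learning_rate_dual * dual_sessions_completed)
    acc <- acc - eff
  }
  clamp(acc, 0, 100)
}

#' Population configuration for cohort sampling
#'
#' Means and between-subject standard deviations of every observer
#' parameter, plus group sizes. Defaults emulate a two-arm randomized cohort
#' of 19 multitask-trained and 20 single-task-trained participants whose
#' component tasks are thresholded to ~80% accuracy, whose baseline overall
#' dual-task accuracy cost is ~15.6 percentage points, and whose cost falls
#' by ~1.2 points per dual-training session (multitask group only).
#'
#' @param n_per_group Named integer vector `c(multitask = , single = )`.
#' @param means,sds Named lists overriding individual parameter means / SDs.
#' @param transfer A [transfer_effect_params()] describing the transfer
#'   battery's generative effects.
#' @return A `population_config` list.
#' @export
population_config <- function(n_per_group = c(multitask = 19L, single = 20L),
                              means = list(), sds = list(),
                              transfer = transfer_effect_params()) {
  stopifnot(all(n_per_group >= 1),
            all(c("multitask", "single") %in% names(n_per_group)))
  base_means <- list(
    track_midpoint = 0.092, track_slope = 130,
    discrim_midpoint = 450, discrim_slope = 0.013,
    lapse = 0.01, rt_shift = 100, rt_meanlog = log(220), rt_sdlog = 0.25,
    rt_interference = 13, false_alarm_rate = 0.05,
    interference_track = 0, interference_discrim = 15.6,
    learning_track = 0.00055, learning_discrim = 4.2,
    learning_rate_dual = 1.2
  )
  base_sds <- list(
    track_midpoint = 0.008, track_slope = 15,
    discrim_midpoint = 40, discrim_slope = 0.002,
    lapse = 0.005, rt_shift = 15, rt_meanlog = 0.06, rt_sdlog = 0.03,
    rt_interference = 8, false_alarm_rate = 0.02,
    interference_track = 0, interference_discrim = 5,
    learning_track = 0.0002, learning_discrim = 1.5,
    learning_rate_dual = 0.4
  )
  unknown <- setdiff(c(names(means), names(sds)), names(base_means))
  if (length(unknown)) {
    stop("unknown observer parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  base_means[names(means)] <- means
  base_sds[names(sds)] <- sds
  if (any(unlist(base_sds) < 0)) {
    stop("population dispersions must be non-negative", call. = FALSE)
  }
  structure(
    list(n_per_group = n_per_group, means = base_means, sds = base_sds,
         transfer = transfer),
    class = "population_config"
  )
}

# Parameter-specific truncation keeps sampled observers valid.
observer_bounds <- list(
  track_midpoint = c(0.0100, 0.1120), track_slope = c(1e-6, Inf),
  discrim_midpoint = c(250, 1000), discrim_slope = c(1e-9, Inf),
  lapse = c(0, 0.05), rt_shift = c(0, Inf), rt_meanlog = c(-Inf, Inf),
  rt_sdlog = c(0, Inf), rt_interference = c(0, Inf),
  false_alarm_rate = c(0, 1), interference_track = c(0, 100),
  interference_discrim = c(0, 100), learning_track = c(0, Inf),
  learning_discrim = c(0, Inf), learning_rate_dual = c(0, Inf)
)

#' Sample a randomized cohort of synthetic observers
#'
#' Draws each observer parameter independently from a normal distribution
#' (truncated to its valid range) and randomizes group assignment, so group
#' membership is independent of every generative parameter. Each observer
#' also receives a personal transfer-task profile drawn around the
#' population-level transfer effects.
#'
#' @param cfg A [population_config()].
#' @param seed Integer seed.
#' @return A list of [observer_params()], of length `sum(cfg$n_per_group)`.
#' @export
#' @examples
#' length(sample_population(population_config(), seed = 1))  # 39
sample_population <- function(cfg = population_config(), seed = 1L) {
  stopifnot(inherits(cfg, "population_config"))
  set.seed(seed)
  n_total <- sum(cfg$n_per_group)
  groups <- sample(rep(names(cfg$n_per_group), cfg$n_per_group))
  ids <- sprintf("p%02d", seq_len(n_total))
  lapply(seq_len(n_total), function(i) {
    draws <- lapply(names(cfg$means), function(par) {
      b <- observer_bounds[[par]]
      clamp(stats::rnorm(1, cfg$means[[par]], cfg$sds[[par]]), b[1], b[2])
    })
    names(draws) <- names(cfg$means)
    profile <- sample_transfer_profile(cfg$transfer)
    do.call(observer_params,
            c(list(id = ids[i], group = groups[i], transfer = profile),
              draws))
  })
}
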