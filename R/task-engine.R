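#' Tracking task parameters
#'
#' Geometry and kinematics of the continuous pursuit-tracking task: a target
#' disc moves at constant speed across a 1024 x 768 pixel arena, reflecting
#' specularly off the display edges and off two invisible discs, with a 1 cm
#' protective zone around the screen centre (where the discrimination shapes
#' appear) treated as a third reflective obstacle. The x and y velocity
#' components are updated independently. Pixel/centimetre conversion assumes
#' a 57 cm viewing distance (1 cm on screen is about 1 degree of visual
#' angle) at `px_per_cm` pixels per centimetre.
#'
#' @param target_speed Ladder speed value (dps).
#' @param target_radius,cursor_radius Disc radii in degrees.
#' @param arena Pixel bounds `c(width, height)`.
#' @param px_per_cm Pixels per centimetre of screen.
#' @param protective_radius_cm No-go radius around the screen centre (cm).
#' @param obstacle_radius_cm Radius of the two invisible bounce discs (cm).
#' @param tick Kinematic step (s); 0.01 matches a 100 Hz refresh.
#' @param speed_px_scale Pixels moved per tick per unit of ladder speed.
#' @param start_heading Optional initial heading (radians); drawn at random
#'   if `NULL`.
#' @return A `tracking_params` list.
#' @export
tracking_params <- function(target_speed, target_radius = 0.50,
                            cursor_radius = 0.10, arena = c(1024, 768),
                            px_per_cm = 30, protective_radius_cm = 1,
                            obstacle_radius_cm = 1, tick = 0.01,
                            speed_px_scale = 100, start_heading = NULL) {
  stopifnot(target_speed > 0, tick > 0, length(arena) == 2, all(arena > 0))
  structure(
    list(target_speed = target_speed, target_radius = target_radius,
         cursor_radius = cursor_radius, arena = arena, px_per_cm = px_per_cm,
         protective_radius_cm = protective_radius_cm,
         obstacle_radius_cm = obstacle_radius_cm, tick = tick,
         speed_px_scale = speed_px_scale, start_heading = start_heading),
    class = "tracking_params"
  )
}

#' Discrimination task parameters
#'
#' @param rt_window Response window (ms) within which a key press to a
#'   target counts as correct; the ladder's difficulty parameter.
#' @param stimulus_duration Shape on-screen time (ms).
#' @param onset_intervals Inter-onset intervals (ms) drawn uniformly.
#' @param p_target Probability that a presented shape is the trial's target.
#' @param n_stimulus_types Number of colour-by-shape combinations.
#' @return A `discrimination_params` list.
#' @export
discrimination_params <- function(rt_window, stimulus_duration = 400,
                                  onset_intervals = c(2000, 2500, 3000),
                                  p_target = 0.5, n_stimulus_types = 12L) {
  stopifnot(rt_window >= 250, rt_window <= 1000,
            p_target >= 0, p_target <= 1, length(onset_intervals) >= 1,
            all(onset_intervals > 0), n_stimulus_types >= 2)
  structure(
    list(rt_window = rt_window, stimulus_duration = stimulus_duration,
         onset_intervals = onset_intervals, p_target = p_target,
         n_stimulus_types = as.integer(n_stimulus_types)),
    class = "discrimination_params"
  )
}

#' Generate a bouncing target trajectory
#'
#' Produces a piecewise-linear constant-speed path: at each tick the target
#' advances `target_speed * speed_px_scale` pixels along its heading, with
#' specular (angle-in equals angle-out) reflection off the arena edges and
#' off the obstacle discs (the two invisible discs plus the central
#' protective zone). The target starts at the top centre of the arena.
#'
#' @param params A [tracking_params()].
#' @param duration Path duration (s).
#' @param seed Optional integer seed (fixes the initial heading).
#' @return A tibble with columns `t` (s), `x`, `y` (pixels).
#' @export
generate_trajectory <- function(params, duration, seed = NULL) {
  stopifnot(inherits(params, "tracking_params"))
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  w <- params$arena[1]; h <- params$arena[2]
  margin <- params$target_radius * params$px_per_cm
  step <- params$target_speed * params$speed_px_scale
  r_obs <- params$obstacle_radius_cm * params$px_per_cm
  r_prot <- params$protective_radius_cm * params$px_per_cm
  # obstacle centres: two invisible discs plus the central protective zone
  obs <- rbind(c(w / 3, h / 2), c(2 * w / 3, h / 2), c(w / 2, h / 2))
  obs_r <- c(r_obs, r_obs, r_prot)
  n <- floor(duration / params$tick)
  x <- numeric(n + 1); y <- numeric(n + 1)
  x[1] <- w / 2; y[1] <- h - margin
  theta <- params$start_heading %||% stats::runif(1, pi + pi / 6, 2 * pi - pi / 6)
  vx <- step * cos(theta); vy <- step * sin(theta)
  for (i in seq_len(n)) {
    for (k in 1:4) { # allow a few reflections within one tick
      nx <- x[i] + vx; ny <- y[i] + vy
      bounced <- FALSE
      if (nx < margin || nx > w - margin) { vx <- -vx; bounced <- TRUE }
      if (ny < margin || ny > h - margin) { vy <- -vy; bounced <- TRUE }
      if (!bounced) {
        for (j in seq_along(obs_r)) {
          dx <- nx - obs[j, 1]; dy <- ny - obs[j, 2]
          if (dx * dx + dy * dy < obs_r[j]^2) {
            # reflect the velocity about the surface normal at the
            # current (outside) position
            ux <- x[i] - obs[j, 1]; uy <- y[i] - obs[j, 2]
            nrm <- sqrt(ux * ux + uy * uy)
            if (nrm < 1e-12) { vx <- -vx; vy <- -vy } else {
              ux <- ux / nrm; uy <- uy / nrm
              dot <- vx * ux + vy * uy
              vx <- vx - 2 * dot * ux
              vy <- vy - 2 * dot * uy
            }
            bounced <- TRUE
            break
          }
        }
      }
      if (!bounced) break
    }
    x[i + 1] <- x[i] + vx
    y[i + 1] <- y[i] + vy
  }
  tibble::tibble(t = params$tick * (0:n), x = x, y = y)
}

# Fast internal schedule representation (vectors, no tibble).
make_schedule <- function(params, duration) {
  dur_ms <- duration * 1000
  max_n <- ceiling(dur_ms / min(params$onset_intervals)) + 1
  gaps <- sample(params$onset_intervals, max_n, replace = TRUE)
  onset <- c(0, cumsum(gaps))  # first shape at trial start, then every gap
  onset <- onset[onset + params$stimulus_duration <= dur_ms]
  n <- length(onset)
  is_target <- stats::runif(n) < params$p_target
  target_id <- sample.int(params$n_stimulus_types, 1)
  stimulus <- 1 + (target_id - 1 +
                     sample.int(params$n_stimulus_types - 1, n,
                                replace = TRUE)) %% params$n_stimulus_types
  stimulus[is_target] <- target_id
  list(onset = onset, stimulus = stimulus, is_target = is_target)
}

#' Generate a stimulus schedule for the discrimination task
#'
#' The first shape appears at trial start and successive onsets are
#' separated by an interval drawn uniformly from `onset_intervals`; each
#' shape is the trial's (fixed) target with probability `p_target`,
#' otherwise a random distractor.
#'
#' @inheritParams generate_trajectory
#' @param params A [discrimination_params()].
#' @return A tibble with columns `onset` (ms), `stimulus` (id), `is_target`.
#' @export
generate_stimulus_schedule <- function(params, duration, seed = NULL) {
  stopifnot(inherits(params, "discrimination_params"))
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  s <- make_schedule(params, duration)
  tibble::tibble(onset = s$onset, stimulus = s$stimulus,
                 is_target = s$is_target)
}

#' Score a discrimination trial
#'
#' A target is correct iff some response falls within
#' `[onset, onset + rt_window]`; a distractor is correct iff no response
#' falls in its window. Accuracy is correct events over all presented
#' shapes; mean RT is taken over correct target responses only.
#'
#' @param schedule A schedule tibble from [generate_stimulus_schedule()].
#' @param responses Numeric vector of response times (ms), sorted.
#' @param params A [discrimination_params()].
#' @return A list with `accuracy` (percent) and `mean_rt` (ms; `NA` if no
#'   correct target response).
#' @export
#' @examples
#' p <- discrimination_params(rt_window = 500)
#' sched <- generate_stimulus_schedule(p, 60, seed = 1)
#' score_discrimination(sched, sched$onset[sched$is_target] + 100, p)
score_discrimination <- function(schedule, responses, params) {
  stopifnot(inherits(params, "discrimination_params"))
  if (is.unsorted(responses)) stop("responses must be time-sorted", call. = FALSE)
  n <- length(schedule$onset)
  if (n == 0) stop("empty stimulus schedule", call. = FALSE)
  if (length(responses) && any(responses < schedule$onset[1])) {
    warning("ignoring response(s) before the first stimulus onset",
            call. = FALSE)
    responses <- responses[responses >= schedule$onset[1]]
  }
  # first response at or after each onset (windows never overlap: minimum
  # inter-onset interval 2000 ms exceeds the maximum 1000 ms window)
  idx <- findInterval(schedule$onset - 1e-9, responses) + 1
  rt <- rep(Inf, n)
  has <- idx <= length(responses)
  rt[has] <- responses[idx[has]] - schedule$onset[has]
  hit <- rt <= params$rt_window
  correct <- !schedule$is_target
  correct[schedule$is_target] <- hit[schedule$is_target]
  correct[!schedule$is_target] <- !hit[!schedule$is_target]
  target_rts <- rt[schedule$is_target & hit]
  list(accuracy = 100 * mean(correct),
       mean_rt = if (length(target_rts)) mean(target_rts) else NA_real_)
}

# Truncated shifted log-normal response times (ms), bounded by the window.
draw_rts <- function(n, observer, rt_window, dual) {
  if (n == 0) return(numeric(0))
  shift <- observer$rt_shift + if (dual) observer$rt_interference else 0
  rt <- shift + stats::rlnorm(n, observer$rt_meanlog, observer$rt_sdlog)
  over <- rt > rt_window
  if (any(over)) {
    rt[over] <- shift +
      stats::rlnorm(sum(over), observer$rt_meanlog, observer$rt_sdlog)
  }
  pmin(rt, rt_window)
}

# Simulate one trial; returns a plain named list (hot path for cohort runs).
run_trial_core <- function(observer, condition, tracking, discrimination,
                           duration, sessions_completed = 0,
                           dual_sessions_completed = 0) {
  dual <- condition == "dual"
  track_acc <- NA_real_; disc_acc <- NA_real_; mean_rt <- NA_real_
  if (condition == "single_tracking" && !is.null(discrimination)) {
    # ignored shape stream: presented for stimulation equivalence, unscored
    invisible(make_schedule(discrimination, duration))
  }
  if (condition %in% c("single_tracking", "dual")) {
    e <- psychometric_accuracy(observer, "tracking", tracking$target_speed,
                               dual = dual,
                               sessions_completed = sessions_completed,
                               dual_sessions_completed = dual_sessions_completed)
    n_sec <- max(1L, round(duration))
    track_acc <- 100 * stats::rbinom(1, n_sec, e / 100) / n_sec
  }
  if (condition %in% c("single_discrimination", "dual")) {
    sched <- make_schedule(discrimination, duration)
    e <- psychometric_accuracy(observer, "discrimination",
                               discrimination$rt_window, dual = dual,
                               sessions_completed = sessions_completed,
                               dual_sessions_completed = dual_sessions_completed)
    fa <- observer$false_alarm_rate
    p_t <- discrimination$p_target
    # per-event probabilities chosen so the expected overall accuracy
    # equals the psychometric value: p_t * p_hit + (1 - p_t) * (1 - fa)
    p_hit <- if (p_t > 0) clamp((e / 100 - (1 - p_t) * (1 - fa)) / p_t, 0, 1) else 0
    n <- length(sched$onset)
    hit <- sched$is_target & (stats::runif(n) < p_hit)
    false_alarm <- !sched$is_target & (stats::runif(n) < fa)
    respond <- hit | false_alarm
    rts <- numeric(n)
    rts[respond] <- draw_rts(sum(respond), observer,
                             discrimination$rt_window, dual)
    responses <- sort(sched$onset[respond] + rts[respond])
    scored <- score_discrimination(sched, responses, discrimination)
    disc_acc <- scored$accuracy
    mean_rt <- scored$mean_rt
  }
  list(condition = condition, duration = duration,
       tracking_level = NA_integer_, discrim_level = NA_integer_,
       tracking_accuracy = track_acc, discrimination_accuracy = disc_acc,
       mean_rt = mean_rt)
}

#' Simulate one trial of the trained tasks
#'
#' Runs a single-tracking, single-discrimination, or dual trial for an
#' observer and scores it. In the dual condition the observer's effective
#' accuracy on both components is degraded by its interference parameters;
#' in single conditions the irrelevant stream is present on screen but not
#' scored (and not simulated, since it has no consequence for scoring).
#'
#' @param observer An [observer_params()].
#' @param condition `"single_tracking"`, `"single_discrimination"`, or
#'   `"dual"`.
#' @param tracking A [tracking_params()] (required unless the condition is
#'   single discrimination).
#' @param discrimination A [discrimination_params()] (required unless the
#'   condition is single tracking).
#' @param duration Trial duration (s).
#' @param seed Optional integer seed.
#' @param sessions_completed,dual_sessions_completed Learning state; see
#'   [psychometric_accuracy()].
#' @return A one-row tibble: condition, duration, tracking and
#'   discrimination accuracies (percent; `NA` where not scored), and mean RT
#'   (ms) over correct target responses.
#' @export
run_trial <- function(observer, condition = c("single_tracking",
                                              "single_discrimination", "dual"),
                      tracking = NULL, discrimination = NULL, duration = 180,
                      seed = NULL, sessions_completed = 0,
                      dual_sessions_completed = 0) {
  condition <- match.arg(condition)
  stopifnot(inherits(observer, "observer_params"))
  if (condition != "single_discrimination") {
    stopifnot(inherits(tracking, "tracking_params"))
  }
  if (condition != "single_tracking") {
    stopifnot(inherits(discrimination, "discrimination_params"))
  }
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rec <- run_trial_core(observer, condition, tracking, discrimination,
                        duration, sessions_completed,
                        dual_sessions_completed)
  tibble::as_tibble(rec)
}
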