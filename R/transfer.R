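#' Generative parameters for the transfer battery
#'
#' Population-level parameters of the six untrained transfer tasks:
#' psychological refractory period (PRP), six-alternative single response
#' selection (RS), Stroop, attentional blink (AB), go/no-go, and flanker.
#' Each task has a key effect statistic (mean and between-subject SD), a
#' practice shift applied at post-test *identically in both groups* (the
#' null-transfer structure: no session-by-group interaction in expectation),
#' and trial-level noise scales. Defaults are calibrated to the scale of
#' standard effects in healthy young adults: a PRP effect of ~213 ms, an AB
#' magnitude of ~22 points, Stroop/flanker congruency effects of ~122/92 ms,
#' ~20% commission errors and ~318 ms go RTs, and ~631 ms RS responses.
#'
#' @param prp_effect,ab_magnitude,stroop_effect,flanker_effect,commission_rate,go_rt,rs_rt
#'   Population means of the key statistics (ms, percentage points, or `%`).
#' @param between_sd Named list of between-subject SDs of those statistics.
#' @param session_shift Named list of post-training practice shifts (same
#'   sign convention as the statistic; applied to both groups).
#' @param rt_noise Named list of trial-level RT noise SDs (ms).
#' @return A `transfer_effect_params` list.
#' @export
transfer_effect_params <- function(prp_effect = 213, ab_magnitude = 22,
                                   stroop_effect = 122, flanker_effect = 92,
                                   commission_rate = 20, go_rt = 318,
                                   rs_rt = 631,
                                   between_sd = list(), session_shift = list(),
                                   rt_noise = list()) {
  stopifnot(prp_effect >= 0, ab_magnitude >= -100, ab_magnitude <= 100,
            stroop_effect >= 0, flanker_effect >= 0,
            commission_rate >= 0, commission_rate <= 100, go_rt > 0,
            rs_rt > 0)
  sd_def <- list(prp_effect = 120, ab_magnitude = 14, stroop_effect = 84,
                 flanker_effect = 41, commission_rate = 14, go_rt = 35,
                 rs_rt = 85)
  shift_def <- list(prp_effect = -20.8, ab_magnitude = -1.8,
                    stroop_effect = -23.6, flanker_effect = -3.9,
                    commission_rate = 5.6, go_rt = -18.8, rs_rt = -46.7)
  noise_def <- list(prp = 150, rs = 120, stroop = 120, flanker = 110,
                    gonogo = 60)
  for (nm in names(between_sd)) sd_def[[nm]] <- between_sd[[nm]]
  for (nm in names(session_shift)) shift_def[[nm]] <- session_shift[[nm]]
  for (nm in names(rt_noise)) noise_def[[nm]] <- rt_noise[[nm]]
  if (any(unlist(sd_def) < 0) || any(unlist(noise_def) <= 0)) {
    stop("transfer SDs must be >= 0 and noise scales > 0", call. = FALSE)
  }
  structure(
    list(means = list(prp_effect = prp_effect, ab_magnitude = ab_magnitude,
                      stroop_effect = stroop_effect,
                      flanker_effect = flanker_effect,
                      commission_rate = commission_rate, go_rt = go_rt,
                      rs_rt = rs_rt),
         between_sd = sd_def, session_shift = shift_def, rt_noise = noise_def,
         # fixed task geometry: blocks x trials per block, lags, no-go rate
         design = list(prp = c(4, 40), rs = c(4, 36), stroop = c(4, 36),
                       ab = c(4, 24), gonogo = c(4, 36), flanker = c(4, 36),
                       ab_lags = c(2, 3, 5, 7), p_nogo = 0.25),
         base = list(prp_rt1 = 600, prp_rt2 = 650, prp_acc = 0.93,
                     rs_acc = 0.92, stroop_rt = 650, stroop_acc = 0.95,
                     flanker_rt = 600, flanker_acc = 0.95,
                     ab_t1_acc = 0.85, ab_t2_long = 0.80, go_resp = 0.97)),
    class = "transfer_effect_params"
  )
}

# One observer's personal transfer-task means, drawn around the population
# effects. Rates are truncated to their natural ranges.
sample_transfer_profile <- function(effects) {
  if (is.null(effects)) return(NULL)
  stopifnot(inherits(effects, "transfer_effect_params"))
  draw <- function(nm, lo = -Inf, hi = Inf) {
    clamp(stats::rnorm(1, effects$means[[nm]], effects$between_sd[[nm]]),
          lo, hi)
  }
  list(prp_effect = draw("prp_effect"),
       ab_magnitude = draw("ab_magnitude", -100, 100),
       stroop_effect = draw("stroop_effect"),
       flanker_effect = draw("flanker_effect"),
       commission_rate = draw("commission_rate", 0, 100),
       go_rt = draw("go_rt", 50, Inf),
       rs_rt = draw("rs_rt", 100, Inf))
}

#' Generate trial tables for the six transfer tasks
#'
#' Draws trial-level data for one observer and one session such that the
#' expected value of each task's key statistic equals the observer's personal
#' parameter (plus, at post-test, the population practice shift, which is
#' identical across groups). Tables are generated at the trial-statistic
#' level: RTs and accuracies, not stimulus renderings.
#'
#' @param observer An [observer_params()] carrying a transfer profile.
#' @param effects A [transfer_effect_params()].
#' @param session `"pre"` or `"post"`.
#' @param seed Optional integer seed.
#' @return A named list of tibbles (`prp`, `single_rs`, `stroop`, `ab`,
#'   `gonogo`, `flanker`), each keyed by `participant_id`, `group`, `task`,
#'   `session`.
#' @export
generate_transfer_tables <- function(observer, effects = transfer_effect_params(),
                                     session = c("pre", "post"), seed = NULL) {
  session <- match.arg(session)
  stopifnot(inherits(effects, "transfer_effect_params"))
  profile <- observer$transfer
  if (is.null(profile)) {
    stop("observer has no transfer profile; sample it via sample_population()",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  post <- session == "post"
  shift <- function(nm) if (post) effects$session_shift[[nm]] else 0
  des <- effects$design
  base <- effects$base
  key <- function(tab, task) {
    tibble::as_tibble(c(list(participant_id = observer$id,
                             group = observer$group, task = task,
                             session = session), tab))
  }

  # PRP: two SOAs, task-2 RT slowed at the short SOA by the personal effect.
  n <- prod(des$prp)
  soa <- sample(rep(c(200L, 1000L), n / 2))
  eff <- profile$prp_effect + shift("prp_effect")
  prp <- key(list(
    block = rep(seq_len(des$prp[1]), each = des$prp[2]),
    trial = seq_len(n), soa = soa,
    rt1 = base$prp_rt1 + stats::rnorm(n, 0, effects$rt_noise$prp),
    correct1 = stats::rbinom(n, 1, base$prp_acc) == 1,
    rt2 = base$prp_rt2 + eff * (soa == 200L) +
      stats::rnorm(n, 0, effects$rt_noise$prp),
    correct2 = stats::rbinom(n, 1, base$prp_acc) == 1
  ), "prp")

  # Single response selection: one speeded RT per trial.
  n <- prod(des$rs)
  rs <- key(list(
    block = rep(seq_len(des$rs[1]), each = des$rs[2]), trial = seq_len(n),
    rt = profile$rs_rt + shift("rs_rt") +
      stats::rnorm(n, 0, effects$rt_noise$rs),
    correct = stats::rbinom(n, 1, base$rs_acc) == 1
  ), "single_rs")

  congruency_table <- function(dims, base_rt, acc, eff, noise, task) {
    n <- prod(dims)
    type <- sample(rep(c("congruent", "incongruent", "neutral"), n / 3))
    key(list(
      block = rep(seq_len(dims[1]), each = dims[2]), trial = seq_len(n),
      trial_type = type,
      rt = base_rt + eff * (type == "incongruent") +
        (eff / 2) * (type == "neutral") + stats::rnorm(n, 0, noise),
      correct = stats::rbinom(n, 1, acc) == 1
    ), task)
  }
  stroop <- congruency_table(des$stroop, base$stroop_rt, base$stroop_acc,
                             profile$stroop_effect + shift("stroop_effect"),
                             effects$rt_noise$stroop, "stroop")
  flanker <- congruency_table(des$flanker, base$flanker_rt, base$flanker_acc,
                              profile$flanker_effect + shift("flanker_effect"),
                              effects$rt_noise$flanker, "flanker")

  # AB: T2|T1 accuracy depressed at lags 2-3 by the personal magnitude.
  n <- prod(des$ab)
  lag <- sample(rep(des$ab_lags, n / length(des$ab_lags)))
  mag <- profile$ab_magnitude + shift("ab_magnitude")
  p2 <- clamp(base$ab_t2_long - (mag / 100) * (lag %in% c(2, 3)), 0, 1)
  ab <- key(list(
    block = rep(seq_len(des$ab[1]), each = des$ab[2]), trial = seq_len(n),
    lag = lag,
    t1_correct = stats::rbinom(n, 1, base$ab_t1_acc) == 1,
    t2_correct = stats::rbinom(n, 1, p2) == 1
  ), "ab")

  # Go/no-go: commissions on no-go trials, speeded RTs on go trials.
  n <- prod(des$gonogo)
  n_nogo <- round(n * des$p_nogo)
  go <- sample(rep(c(TRUE, FALSE), c(n - n_nogo, n_nogo)))
  p_resp <- ifelse(go, base$go_resp,
                   clamp((profile$commission_rate +
                            shift("commission_rate")) / 100, 0, 1))
  responded <- stats::rbinom(n, 1, p_resp) == 1
  rt <- ifelse(responded,
               profile$go_rt + shift("go_rt") +
                 stats::rnorm(n, 0, effects$rt_noise$gonogo),
               NA_real_)
  gonogo <- key(list(
    block = rep(seq_len(des$gonogo[1]), each = des$gonogo[2]),
    trial = seq_len(n), go = go, responded = responded, rt = rt
  ), "gonogo")

  list(prp = prp, single_rs = rs, stroop = stroop, ab = ab,
       gonogo = gonogo, flanker = flanker)
}
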