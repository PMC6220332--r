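#' Assemble a run configuration
#'
#' Bundles everything a simulation run needs -- population, staircase,
#' protocol, and transfer-battery parameters plus the master seed -- into
#' one validated object that round-trips losslessly through YAML. All
#' per-stage seeds are derived from the master seed with [derive_seed()].
#'
#' @param population A [population_config()].
#' @param protocol A [protocol_config()].
#' @param seed Master integer seed.
#' @return A `dts_run_config` list.
#' @export
run_config <- function(population = population_config(),
                       protocol = protocol_config(), seed = 1L) {
  stopifnot(inherits(population, "population_config"),
            inherits(protocol, "protocol_config"),
            is.numeric(seed), length(seed) == 1)
  structure(list(population = population, protocol = protocol,
                 seed = as.integer(seed)),
            class = "dts_run_config")
}

#' Default run configuration
#'
#' The study conditions simulated by default: 19 multitask-trained and 20
#' single-task-trained observers, both component tasks thresholded to ~80%
#' accuracy over nine staircase trials, five 3-minute test trials per
#' condition, six 12-trial training sessions, and the six-task transfer
#' battery.
#'
#' @param seed Master integer seed.
#' @return A `dts_run_config`.
#' @export
default_config <- function(seed = 1L) {
  run_config(seed = seed)
}

config_to_list <- function(cfg) {
  stopifnot(inherits(cfg, "dts_run_config"))
  pop <- cfg$population
  pr <- cfg$protocol
  sc <- pr$staircase
  tr <- pop$transfer
  list(
    seed = cfg$seed,
    population = list(n_per_group = as.list(pop$n_per_group),
                      means = pop$means, sds = pop$sds),
    transfer = list(means = tr$means, between_sd = tr$between_sd,
                    session_shift = tr$session_shift, rt_noise = tr$rt_noise),
    staircase = list(criterion = sc$criterion, deadband_low = sc$deadband_low,
                     deadband_high = sc$deadband_high, gain = sc$gain,
                     start_level = sc$start_level,
                     n_threshold_trials = sc$n_threshold_trials),
    protocol = list(
      n_test_trials = pr$n_test_trials, test_duration = pr$test_duration,
      n_training_sessions = pr$n_training_sessions,
      trials_per_training_session = pr$trials_per_training_session,
      training_duration = pr$training_duration,
      thresh_duration_tracking = pr$thresh_duration_tracking,
      thresh_duration_discrim = pr$thresh_duration_discrim,
      bonus_dual_criterion = pr$bonus_dual_criterion,
      bonus_single_criterion = pr$bonus_single_criterion,
      include_training = pr$include_training,
      include_transfer = pr$include_transfer))
}

check_keys <- function(lst, allowed, where) {
  unknown <- setdiff(names(lst), allowed)
  if (length(unknown)) {
    stop("unknown configuration key(s) in ", where, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
}

list_to_config <- function(lst) {
  check_keys(lst, c("seed", "population", "transfer", "staircase",
                    "protocol"), "top level")
  p <- lst$population %||% list()
  check_keys(p, c("n_per_group", "means", "sds"), "population")
  t <- lst$transfer %||% list()
  check_keys(t, c("means", "between_sd", "session_shift", "rt_noise"),
             "transfer")
  tmeans <- t$means %||% list()
  check_keys(tmeans,
             c("prp_effect", "ab_magnitude", "stroop_effect",
               "flanker_effect", "commission_rate", "go_rt", "rs_rt"),
             "transfer$means")
  transfer <- do.call(transfer_effect_params,
                      c(tmeans,
                        list(between_sd = t$between_sd %||% list(),
                             session_shift = t$session_shift %||% list(),
                             rt_noise = t$rt_noise %||% list())))
  npg <- p$n_per_group %||% list(multitask = 19L, single = 20L)
  population <- population_config(
    n_per_group = c(multitask = as.integer(npg$multitask),
                    single = as.integer(npg$single)),
    means = p$means %||% list(), sds = p$sds %||% list(),
    transfer = transfer)
  s <- lst$staircase %||% list()
  check_keys(s, c("criterion", "deadband_low", "deadband_high", "gain",
                  "start_level", "n_threshold_trials"), "staircase")
  staircase <- do.call(staircase_config, s)
  pr <- lst$protocol %||% list()
  check_keys(pr, c("n_test_trials", "test_duration", "n_training_sessions",
                   "trials_per_training_session", "training_duration",
                   "thresh_duration_tracking", "thresh_duration_discrim",
                   "bonus_dual_criterion", "bonus_single_criterion",
                   "include_training", "include_transfer"), "protocol")
  protocol <- do.call(protocol_config, c(list(staircase = staircase), pr))
  run_config(population = population, protocol = protocol,
             seed = lst$seed %||% 1L)
}

#' Read or write a run configuration as YAML
#'
#' `load_config()` rejects unknown keys and re-validates every parameter
#' through the constructors, reporting the offending field on failure.
#'
#' @param path YAML file path.
#' @param cfg A `dts_run_config`.
#' @return `load_config()` returns a validated `dts_run_config`;
#'   `save_config()` returns `path` invisibly.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  list_to_config(yaml::read_yaml(path))
}

#' @rdname load_config
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(config_to_list(cfg), path)
  invisible(path)
}
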