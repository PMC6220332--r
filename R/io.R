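#' Analyze a simulated cohort
#'
#' Runs the full outcome/inference layer on a cohort: per-participant cost
#' summaries, the session-by-group mixed ANOVA (with BIC Bayes factors) on
#' the overall dual-task cost, transfer-effect summaries with their
#' interaction tests, and the a-priori exclusion rule.
#'
#' @param cohort A `dts_cohort` from [run_cohort()].
#' @return A list: `costs`, `cost_anova`, `cost_bf`, `transfer_summaries`,
#'   `transfer_tests`, `exclusions`, `tables`.
#' @export
analyze_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "dts_cohort"))
  costs <- cohort_costs(cohort$trials)
  wide <- costs_wide(costs, "overall_cost")
  cost_anova <- mixed_anova_2x2(wide)
  cost_bf <- bf_mixed_anova(wide)
  transfer_summaries <- NULL; transfer_tests <- NULL; exclusions <- NULL
  if (!is.null(cohort$transfer)) {
    transfer_summaries <- transfer_summary(cohort$transfer)
    measures <- setdiff(names(transfer_summaries),
                        c("participant_id", "group", "session"))
    transfer_tests <- dplyr::bind_rows(lapply(measures, function(ms) {
      w <- transfer_summaries |>
        dplyr::select("participant_id", "group", "session",
                      value = dplyr::all_of(ms)) |>
        tidyr::pivot_wider(names_from = "session", values_from = "value")
      an <- mixed_anova_2x2(w)
      an$measure <- ms
      an
    }))
    if (nrow(cohort$participants) >= 3) {
      exclusions <- apply_exclusions(cohort$transfer)
    }
  }
  tables <- reproduce_design_tables(costs, transfer_summaries)
  list(costs = costs, cost_anova = cost_anova, cost_bf = cost_bf,
       transfer_summaries = transfer_summaries,
       transfer_tests = transfer_tests, exclusions = exclusions,
       tables = tables)
}

write_csv_plain <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE)
  path
}

#' Write run artifacts and a manifest
#'
#' Writes the cohort's trial tables, per-task transfer tables, participant
#' metadata, and (optionally) analysis outputs as CSV/JSON, plus a
#' `manifest.json` listing every emitted file exactly once with its MD5
#' checksum, the master seed, and the package version. File contents are
#' deterministic for a fixed seed, so two identical runs produce identical
#' manifests.
#'
#' @param cohort A `dts_cohort`.
#' @param out_dir Output directory (created if missing).
#' @param analysis Optional result of [analyze_cohort()].
#' @return The manifest (invisibly), as written to `manifest.json`.
#' @export
write_outputs <- function(cohort, out_dir, analysis = NULL) {
  stopifnot(inherits(cohort, "dts_cohort"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  files <- c(files, write_csv_plain(cohort$trials,
                                    file.path(out_dir, "cohort_trials.csv")))
  files <- c(files, write_csv_plain(cohort$participants,
                                    file.path(out_dir, "participants.csv")))
  if (!is.null(cohort$transfer)) {
    for (task in names(cohort$transfer)) {
      files <- c(files, write_csv_plain(
        cohort$transfer[[task]],
        file.path(out_dir, paste0("transfer_", task, ".csv"))))
    }
  }
  if (!is.null(analysis)) {
    files <- c(files, write_csv_plain(analysis$costs,
                                      file.path(out_dir, "costs.csv")))
    files <- c(files, write_csv_plain(analysis$cost_anova,
                                      file.path(out_dir, "anova.csv")))
    bayes <- tibble::tibble(bf10 = analysis$cost_bf$bf10,
                            bf20 = analysis$cost_bf$bf20,
                            bf12 = analysis$cost_bf$bf12)
    files <- c(files, write_csv_plain(bayes, file.path(out_dir, "bayes.csv")))
    if (!is.null(analysis$transfer_summaries)) {
      files <- c(files, write_csv_plain(
        analysis$transfer_summaries,
        file.path(out_dir, "transfer_summary.csv")))
      files <- c(files, write_csv_plain(
        analysis$transfer_tests, file.path(out_dir, "transfer_tests.csv")))
    }
    if (!is.null(analysis$exclusions)) {
      path <- file.path(out_dir, "exclusions.json")
      jsonlite::write_json(analysis$exclusions, path, auto_unbox = TRUE,
                           digits = NA)
      files <- c(files, path)
    }
  }
  manifest <- list(
    package = "dualtasksim",
    version = as.character(utils::packageVersion("dualtasksim")),
    seed = cohort$seed,
    n_participants = nrow(cohort$participants),
    n_trials = nrow(cohort$trials),
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Simulate a full run from a configuration
#'
#' Convenience wrapper tying the pipeline together: samples the cohort,
#' runs the protocol, and (optionally) writes all artifacts.
#'
#' @param cfg A `dts_run_config` (see [run_config()], [load_config()]).
#' @param out_dir Optional output directory for [write_outputs()].
#' @param analyze Also run [analyze_cohort()] and include its outputs.
#' @return A list with `cohort`, and `analysis`/`manifest` when requested.
#' @export
simulate_run <- function(cfg = default_config(), out_dir = NULL,
                         analyze = TRUE) {
  stopifnot(inherits(cfg, "dts_run_config"))
  cohort <- run_cohort(cfg$population, cfg$protocol, seed = cfg$seed)
  analysis <- if (analyze) analyze_cohort(cohort)
  manifest <- NULL
  if (!is.null(out_dir)) {
    manifest <- write_outputs(cohort, out_dir, analysis)
  }
  list(cohort = cohort, analysis = analysis, manifest = manifest)
}
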