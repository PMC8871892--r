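# End-to-end study orchestration: calibrate -> base case -> scenarios ->
# comparison tables -> reproducibility manifest.

#' Run the full simulation study
#'
#' Executes the whole pipeline: verifies (or performs) calibration, runs the
#' base case and the requested scenarios with common random numbers, builds
#' the percent-change tables for overall turnaround time and hourly crowd,
#' writes all outputs under `out_dir`, and records a run manifest.
#'
#' @param config a [clinic_config()].
#' @param out_dir output directory (`NULL` to skip writing).
#' @param master_seed integer master seed driving every stream.
#' @param n_replications,days experiment scale (defaults 30 x 5).
#' @param scenarios scenario ids to run against the base case.
#' @param calibrate if `TRUE` and the configuration is not calibrated, run
#'   [calibrate_clinic()] first; if `FALSE` an uncalibrated configuration is
#'   an error (`calibrate` names the remedy).
#' @param quiet suppress per-stage progress lines.
#' @return an object of class `"clinic_study"`: `sets` (named list of
#'   [run_experiment()] results, including `base`), `comparisons` (named
#'   list of [compare_scenarios()] results), `tt_change_table`,
#'   `crowd_change_table`, `calibration` (or `NULL`), `manifest`.
#' @export
run_full_study <- function(config = clinic_config(), out_dir = NULL,
                           master_seed = 1, n_replications = 30, days = 5,
                           scenarios = as.character(1:7), calibrate = TRUE,
                           quiet = FALSE) {
  stopifnot(inherits(config, "clinic_config"))
  say <- function(stage, fmt, ...) {
    if (!quiet)
      message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  t_start <- Sys.time()
  calibration <- NULL
  if (!isTRUE(config$calibrated)) {
    if (!calibrate)
      stop("configuration is not calibrated: run `calibrate` ",
           "(calibrate_clinic()) before simulating")
    say("calibrate", "seed %d: searching front-end parameters", master_seed)
    calibration <- calibrate_clinic(config, n_replications = n_replications,
                                    days = days, master_seed = master_seed)
    config <- calibration$config
  }

  sets <- list()
  say("simulate", "base case: %d x %d day(s), seed %d", n_replications, days,
      master_seed)
  sets$base <- run_experiment("base", config, n_replications, days,
                              master_seed)
  for (sc in scenarios) {
    say("simulate", "scenario %s: %d x %d day(s), seed %d", sc,
        n_replications, days, master_seed)
    sets[[sc]] <- run_experiment(sc, config, n_replications, days,
                                 master_seed)
  }

  comparisons <- lapply(sets[scenarios], compare_scenarios, base_set = sets$base)
  tt_change_table <- do.call(rbind, lapply(comparisons, `[[`, "tt_change"))
  crowd_change_table <- do.call(rbind, lapply(comparisons, `[[`, "crowd_change"))

  manifest <- run_manifest(config, master_seed, n_replications, days,
                           c("base", scenarios))
  study <- structure(list(sets = sets, comparisons = comparisons,
                          tt_change_table = tt_change_table,
                          crowd_change_table = crowd_change_table,
                          calibration = calibration, manifest = manifest),
                     class = "clinic_study")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(sets))
      write_replication_set(sets[[nm]], file.path(out_dir, paste0("scenario_", nm)))
    utils::write.csv(data.frame(scenario = rownames(tt_change_table),
                                round(tt_change_table, 2)),
                     file.path(out_dir, "overall_tt_change.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(scenario = rownames(crowd_change_table),
                                round(crowd_change_table, 2),
                                check.names = FALSE),
                     file.path(out_dir, "hourly_crowd_change.csv"),
                     row.names = FALSE)
    jsonlite::write_json(unclass(manifest), file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("write", "outputs in %s", normalizePath(out_dir))
  }
  say("done", "elapsed %.1f s", as.numeric(difftime(Sys.time(), t_start,
                                                    units = "secs")))
  study
}

#' Run manifest
#'
#' Captures everything needed to reproduce a study run: the package version,
#' master seed, experiment scale, scenario list and a digest of the full
#' configuration. Re-running [run_full_study()] with the same configuration
#' and seed reproduces identical outputs.
#'
#' @param config a [clinic_config()].
#' @param master_seed,n_replications,days,scenarios run parameters.
#' @return a named list (class `"run_manifest"`).
#' @export
run_manifest <- function(config, master_seed, n_replications, days,
                         scenarios) {
  structure(list(
    package = "clinicdes",
    version = as.character(utils::packageVersion("clinicdes")),
    master_seed = master_seed,
    n_replications = n_replications,
    days = days,
    scenarios = scenarios,
    config_digest = config_digest(config),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_manifest")
}

#' Deterministic digest of a clinic configuration
#'
#' A 31-bit hash of the canonical JSON serialisation, used by the manifest
#' to detect configuration drift between runs.
#'
#' @param config a [clinic_config()].
#' @return a character digest.
#' @export
config_digest <- function(config) {
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  sprintf("%08x", .str_hash(as.character(js)))
}

#' @export
print.clinic_study <- function(x, ...) {
  cat(sprintf("<clinic_study> base + %d scenario(s), %d x %d day(s), seed %d\n",
              length(x$comparisons), x$manifest$n_replications,
              x$manifest$days, x$manifest$master_seed))
  cat("\nChange in median overall TT vs base (%):\n")
  print(round(x$tt_change_table, 1))
  invisible(x)
}
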