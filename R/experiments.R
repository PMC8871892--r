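# Replication experiments over scenarios and scenario-vs-base comparison.

#' Run a seeded replication experiment for one scenario
#'
#' Simulates `n_replications` independent replications of `days` clinic days
#' under one scenario. Replication `r` uses substreams derived from
#' `(master_seed, r)`, so two experiments sharing a master seed use common
#' random numbers: attribute and service draws align patient-for-patient
#' across scenarios, which sharpens paired comparisons.
#'
#' @param scenario a scenario id accepted by [make_scenario()], or a
#'   `"scenario_config"`.
#' @param config a calibrated [clinic_config()].
#' @param n_replications number of replications (default 30).
#' @param days clinic days per replication (default 5).
#' @param master_seed integer master seed.
#' @param keep_runs retain the individual `"clinic_run"` objects (needed for
#'   event-level export; turnaround and crowd summaries are always kept).
#' @param check_calibrated refuse to run when `config$calibrated` is not
#'   `TRUE` (calibrate first, or pass `FALSE` to override).
#' @return an object of class `"replication_set"`: `scenario`, `tt` (all
#'   patients' turnaround times with a `rep` column), `crowd` (hours x
#'   replications matrix of mean waiting-area counts), `summary` (pooled and
#'   per-replication medians), `runs` (list or `NULL`).
#' @export
run_experiment <- function(scenario = "base", config = clinic_config(),
                           n_replications = 30, days = 5, master_seed = 1,
                           keep_runs = FALSE, check_calibrated = TRUE) {
  if (!inherits(scenario, "scenario_config")) scenario <- make_scenario(scenario)
  stopifnot(inherits(config, "clinic_config"))
  if (n_replications < 1) stop("n_replications must be >= 1")
  if (check_calibrated && !isTRUE(config$calibrated))
    stop("clinic configuration is not calibrated; run calibrate_clinic() ",
         "first or pass check_calibrated = FALSE")
  model <- build_clinic(config, scenario, days)
  tts <- vector("list", n_replications)
  crowd <- NULL
  runs <- if (keep_runs) vector("list", n_replications)
  for (r in seq_len(n_replications)) {
    run <- simulate_replication(model, r, master_seed)
    tt <- turnaround_times(run)
    tt$rep <- r
    tts[[r]] <- tt
    cr <- hourly_crowd(run)
    if (is.null(crowd)) crowd <- matrix(NA_real_, length(cr), n_replications,
                                        dimnames = list(names(cr), NULL))
    crowd[, r] <- cr
    if (keep_runs) runs[[r]] <- run
  }
  tt <- do.call(rbind, tts)
  structure(list(scenario = scenario, config = config,
                 n_replications = n_replications, days = days,
                 master_seed = master_seed, tt = tt, crowd = crowd,
                 summary = .summarise_tt(tt, crowd), runs = runs),
            class = "replication_set")
}

.qtab <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  c(q1 = q[1], median = q[2], q3 = q[3])
}

# pooled (all patients of all replications) and per-replication medians
.summarise_tt <- function(tt, crowd) {
  grp <- list(OBS = tt$class == "OBS", GYN = tt$class == "GYN",
              PUBLIC = tt$class %in% c("OBS", "GYN"),
              PRIVATE = tt$class == "PRIVATE")
  pooled <- lapply(grp, function(sel) {
    if (!any(sel)) return(NULL)
    sapply(c(registration_tt = "registration_tt", clinic_tt = "clinic_tt",
             overall_tt = "overall_tt"),
           function(m) .qtab(tt[[m]][sel]))
  })
  rep_medians <- lapply(grp, function(sel) {
    if (!any(sel)) return(NULL)
    sapply(c(registration_tt = "registration_tt", clinic_tt = "clinic_tt",
             overall_tt = "overall_tt"), function(m)
      tapply(tt[[m]][sel], tt$rep[sel], stats::median))
  })
  list(pooled = pooled, rep_medians = rep_medians,
       crowd_mean = rowMeans(crowd))
}

#' @export
print.replication_set <- function(x, ...) {
  cat(sprintf(
    "<replication_set> scenario %s: %d replications x %d day(s), master seed %d\n",
    x$scenario$id, x$n_replications, x$days, x$master_seed))
  pub <- x$summary$pooled$PUBLIC; priv <- x$summary$pooled$PRIVATE
  cat(sprintf("  public  median TT (reg/clinic/overall): %.0f / %.0f / %.0f min\n",
              pub["median", "registration_tt"], pub["median", "clinic_tt"],
              pub["median", "overall_tt"]))
  cat(sprintf("  private median TT (reg/clinic/overall): %.0f / %.0f / %.0f min\n",
              priv["median", "registration_tt"], priv["median", "clinic_tt"],
              priv["median", "overall_tt"]))
  invisible(x)
}

#' @export
summary.replication_set <- function(object, ...) {
  out <- list(scenario = object$scenario$id,
              pooled = object$summary$pooled,
              crowd_mean = object$summary$crowd_mean)
  class(out) <- "summary.replication_set"
  out
}

#' @export
print.summary.replication_set <- function(x, ...) {
  cat("Scenario:", x$scenario, "\n\nPooled TT quartiles (minutes):\n")
  for (g in names(x$pooled)) {
    if (is.null(x$pooled[[g]])) next
    cat("\n", g, "\n", sep = "")
    print(round(x$pooled[[g]], 1))
  }
  cat("\nMean waiting-area crowd by hour:\n")
  print(round(x$crowd_mean, 2))
  invisible(x)
}

#' Compare a scenario experiment against the base case
#'
#' Percentage change in the pooled median overall turnaround time (per
#' patient group) and in the mean hourly waiting-area crowd, scenario versus
#' base.
#'
#' @param scenario_set,base_set `"replication_set"` objects (the base set
#'   should be the base-case scenario).
#' @return an object of class `"scenario_comparison"`: `tt_change` (percent,
#'   by group), `crowd_change` (percent, by hour; `NA` where the base crowd
#'   is zero), and the underlying medians.
#' @export
compare_scenarios <- function(scenario_set, base_set) {
  stopifnot(inherits(scenario_set, "replication_set"),
            inherits(base_set, "replication_set"))
  groups <- c("OBS", "GYN", "PUBLIC", "PRIVATE")
  med <- function(set, g) set$summary$pooled[[g]]["median", "overall_tt"]
  tt_change <- vapply(groups, function(g)
    percent_change(med(scenario_set, g), med(base_set, g)), 0)
  base_crowd <- base_set$summary$crowd_mean
  scen_crowd <- scenario_set$summary$crowd_mean
  crowd_change <- ifelse(base_crowd > 0,
                         100 * (scen_crowd - base_crowd) / base_crowd,
                         NA_real_)
  structure(list(scenario = scenario_set$scenario$id,
                 base = base_set$scenario$id,
                 tt_change = tt_change,
                 overall_tt_median = vapply(groups, function(g)
                   med(scenario_set, g), 0),
                 base_overall_tt_median = vapply(groups, function(g)
                   med(base_set, g), 0),
                 crowd_change = crowd_change,
                 crowd_mean = scen_crowd, base_crowd_mean = base_crowd),
            class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat(sprintf("<scenario_comparison> scenario %s vs %s\n", x$scenario, x$base))
  cat("  change in median overall TT (%):\n")
  print(round(x$tt_change, 1))
  cat("  change in mean hourly crowd (%):\n")
  print(round(x$crowd_change, 1))
  invisible(x)
}

#' Write a replication set's outputs
#'
#' Writes the per-patient turnaround CSV, the hourly-crowd CSV and a JSON
#' summary into a directory.
#'
#' @param set a `"replication_set"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_replication_set <- function(set, dir) {
  stopifnot(inherits(set, "replication_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(set$tt, file.path(dir, "turnaround_times.csv"),
                   row.names = FALSE)
  crowd <- data.frame(hour = rownames(set$crowd), set$crowd,
                      check.names = FALSE)
  names(crowd)[-1] <- paste0("rep", seq_len(ncol(set$crowd)))
  utils::write.csv(crowd, file.path(dir, "hourly_crowd.csv"),
                   row.names = FALSE)
  pooled_named <- lapply(set$summary$pooled, function(m) {
    if (is.null(m)) return(NULL)
    lapply(stats::setNames(rownames(m), rownames(m)), function(r)
      as.list(m[r, ]))
  })
  summ <- list(scenario = set$scenario$id,
               n_replications = set$n_replications, days = set$days,
               master_seed = set$master_seed,
               pooled = pooled_named,
               crowd_mean = as.list(set$summary$crowd_mean))
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
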