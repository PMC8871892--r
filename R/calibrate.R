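# Base-case calibration of the clinic front end.
#
# The published data pin down the clinic-station process times and the
# turnaround-time (TT) targets, but not the front-end service times (QMS,
# revenue, O&G counter), the walking/in-between times, the EMR-review
# overhead, or the downtime process. Those are free parameters: the
# calibrator searches them so the simulated base case reproduces the
# published TT medians.

#' Published base-case calibration targets
#'
#' The three turnaround-time medians (minutes) the base case must reproduce:
#' public obstetrics registration TT, public obstetrics clinic TT, and
#' private clinic TT.
#'
#' @return a named numeric vector.
#' @export
calibration_targets <- function() {
  c(reg_obs = 45, clin_obs = 99, clin_priv = 66)
}

#' Simulate the base case and report target medians
#'
#' Runs `n_replications` seeded replications of the base case and returns the
#' pooled medians of the three calibration measures (and companions).
#'
#' @param config a [clinic_config()].
#' @param n_replications,days replication count and days per replication.
#' @param master_seed integer master seed.
#' @return named numeric vector with `reg_obs`, `clin_obs`, `clin_priv`
#'   (the calibration measures) plus `reg_gyn`, `clin_gyn`, `reg_priv`,
#'   `overall_pub`, `overall_priv`.
#' @export
evaluate_base_case <- function(config = clinic_config(), n_replications = 30,
                               days = 5, master_seed = 1) {
  model <- build_clinic(config, make_scenario("base"), days)
  tts <- do.call(rbind, lapply(seq_len(n_replications), function(r)
    turnaround_times(simulate_replication(model, r, master_seed))))
  pub <- tts$class %in% c("OBS", "GYN")
  c(reg_obs = stats::median(tts$registration_tt[tts$class == "OBS"]),
    clin_obs = stats::median(tts$clinic_tt[tts$class == "OBS"]),
    clin_priv = stats::median(tts$clinic_tt[tts$class == "PRIVATE"]),
    reg_gyn = stats::median(tts$registration_tt[tts$class == "GYN"]),
    clin_gyn = stats::median(tts$clinic_tt[tts$class == "GYN"]),
    reg_priv = stats::median(tts$registration_tt[tts$class == "PRIVATE"]),
    overall_pub = stats::median(tts$overall_tt[pub]),
    overall_priv = stats::median(tts$overall_tt[tts$class == "PRIVATE"]))
}

# multiplicative parameter setters used by the coordinate search
.calib_setters <- list(
  qms_median = function(cfg, f) {
    cfg$service$QMS <- lapply(cfg$service$QMS, function(q) q * f); cfg
  },
  revenue_median = function(cfg, f) {
    cfg$service$REVENUE <- lapply(cfg$service$REVENUE, function(q) q * f); cfg
  },
  og_counter_median = function(cfg, f) {
    cfg$service$OG_COUNTER <- lapply(cfg$service$OG_COUNTER,
                                     function(q) q * f); cfg
  },
  emr_median = function(cfg, f) { cfg$emr_overhead <- cfg$emr_overhead * f; cfg },
  transfer = function(cfg, f) { cfg$transfer <- cfg$transfer * f; cfg },
  downtime_duration = function(cfg, f) {
    cfg$downtime_duration <- cfg$downtime_duration * f; cfg
  })

#' Calibrate the base-case front end against published medians
#'
#' Coordinate search over multiplicative factors on the free front-end
#' parameters, minimising the maximum relative error of the simulated
#' medians against `targets`. The initial configuration is evaluated first
#' and returned unchanged if it already meets `tolerance` (the shipped
#' [clinic_config()] defaults do). Otherwise each free parameter in turn is
#' scaled over a small factor grid, keeping any improvement, until the
#' tolerance is met or `budget` evaluations are spent; in the latter case
#' the best configuration found is returned with a warning.
#'
#' @param config starting [clinic_config()].
#' @param targets named vector of target medians (minutes); names must be a
#'   subset of the measures returned by [evaluate_base_case()].
#' @param tolerance maximum relative error required on every target
#'   (default 0.10).
#' @param budget maximum number of simulation evaluations.
#' @param free character vector naming the free parameters (see Details).
#' @param n_replications,days,master_seed evaluation scale and seed.
#' @details Free parameters: `qms_median`, `revenue_median`,
#'   `og_counter_median` (front-end service scale), `emr_median`
#'   (EMR-review overhead scale), `transfer` (walking-time scale),
#'   `downtime_duration` (downtime episode length scale).
#' @return an object of class `"clinic_calibration"`: `config` (calibrated),
#'   `achieved`, `targets`, `errors` (relative), `converged`, `n_eval`,
#'   `trace` (one row per evaluation).
#' @export
calibrate_clinic <- function(config = clinic_config(),
                             targets = calibration_targets(),
                             tolerance = 0.10, budget = 40,
                             free = c("qms_median", "revenue_median",
                                      "emr_median", "transfer"),
                             n_replications = 30, days = 5, master_seed = 1) {
  stopifnot(inherits(config, "clinic_config"))
  bad <- setdiff(free, names(.calib_setters))
  if (length(bad)) stop("unknown free parameters: ", paste(bad, collapse = ", "))
  measure_names <- c("reg_obs", "clin_obs", "clin_priv", "reg_gyn",
                     "clin_gyn", "reg_priv", "overall_pub", "overall_priv")
  bad <- setdiff(names(targets), measure_names)
  if (length(bad)) stop("unknown target measures: ", paste(bad, collapse = ", "))
  if (any(targets <= 0)) stop("targets must be positive")

  n_eval <- 0L
  trace <- list()
  score <- function(cfg) {
    n_eval <<- n_eval + 1L
    m <- evaluate_base_case(cfg, n_replications, days, master_seed)
    err <- abs(m[names(targets)] - targets) / targets
    trace[[n_eval]] <<- c(eval = n_eval, max_err = max(err), m[names(targets)])
    list(max_err = max(err), achieved = m[names(targets)], errors = err)
  }

  best_cfg <- config
  best <- score(best_cfg)
  factors <- c(0.7, 0.85, 1.15, 1.4)
  improved <- TRUE
  while (best$max_err > tolerance && n_eval < budget && improved) {
    improved <- FALSE
    for (p in free) {
      if (best$max_err <= tolerance || n_eval >= budget) break
      for (f in factors) {
        if (n_eval >= budget) break
        cand_cfg <- .calib_setters[[p]](best_cfg, f)
        cand <- score(cand_cfg)
        if (cand$max_err < best$max_err) {
          best_cfg <- cand_cfg; best <- cand; improved <- TRUE
        }
      }
    }
  }
  converged <- best$max_err <= tolerance
  if (!converged)
    warning(sprintf(
      "calibration did not reach tolerance %.3g within %d evaluations (best max error %.3g); returning best effort",
      tolerance, budget, best$max_err))
  best_cfg$calibrated <- TRUE
  structure(list(config = best_cfg, achieved = best$achieved,
                 targets = targets, errors = best$errors,
                 converged = converged, tolerance = tolerance,
                 n_eval = n_eval,
                 trace = do.call(rbind, trace)),
            class = "clinic_calibration")
}

#' @export
print.clinic_calibration <- function(x, ...) {
  cat(sprintf("<clinic_calibration> %s after %d evaluation(s)\n",
              if (x$converged) "converged" else "best effort", x$n_eval))
  tab <- data.frame(target = x$targets, achieved = round(x$achieved, 1),
                    rel_error = round(x$errors, 3))
  print(tab)
  invisible(x)
}
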