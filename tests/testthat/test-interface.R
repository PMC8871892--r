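# Configuration I/O, full-study orchestration, manifest reproducibility.

test_that("a clinic configuration round-trips through YAML", {
  cfg <- clinic_config(general_daily = 120L, transfer = 3, calibrated = TRUE)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_clinic_config(cfg, f)
  back <- read_clinic_config(f)
  expect_s3_class(back, "clinic_config")
  expect_identical(back$general_daily, 120L)
  expect_equal(back$transfer, 3)
  expect_equal(back$service, cfg$service)
  expect_equal(back$capacity, cfg$capacity)
  expect_equal(back$rates, cfg$rates)
})

test_that("the shipped default configuration file matches the in-code defaults", {
  f <- system.file("extdata", "default_clinic.yaml", package = "clinicdes")
  expect_true(nzchar(f))
  cfg <- read_clinic_config(f)
  ref <- clinic_config()
  for (nm in names(unclass(ref)))
    expect_equal(cfg[[nm]], ref[[nm]], label = nm)
})

test_that("JSON configs and clock strings are accepted", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(private_session_earliest = "12:45",
                            general_daily = 99),
                       f, auto_unbox = TRUE)
  cfg <- read_clinic_config(f)
  expect_equal(cfg$private_session_earliest, hm("12:45"))
  expect_equal(cfg$general_daily, 99)
  expect_error(clinic_config(bogus_field = 1), "unknown clinic_config fields")
})

test_that("custom scenario configurations are validated", {
  sc <- as_scenario_config(list(id = "custom", arrival_pattern = "even",
                                qms_open = "08:00", consult_start = "08:30",
                                public_slot_cap = 12,
                                last_public_slot = "11:00",
                                private_open = "12:00",
                                private_slot_cap = 3))
  expect_s3_class(sc, "scenario_config")
  expect_equal(sc$qms_open, hm("08:00"))
  expect_false(sc$downtime_enabled)
  expect_error(as_scenario_config(list(id = "x", arrival_pattern = "even")),
               "lacks fields")
  expect_error(as_scenario_config(list(id = "x", arrival_pattern = "blocky",
                                       qms_open = "08:00",
                                       consult_start = "08:30",
                                       public_slot_cap = 12,
                                       last_public_slot = "11:00",
                                       private_open = "12:00",
                                       private_slot_cap = 3)),
               "random")
})

test_that("a small full study runs end to end, writes outputs and reproduces bit-identically", {
  cfg <- clinic_config(general_daily = 40L)
  d1 <- withr::local_tempdir()
  t0 <- Sys.time()
  study <- run_full_study(cfg, out_dir = d1, master_seed = 3,
                          n_replications = 2, days = 1, scenarios = "3",
                          quiet = TRUE)
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  expect_lt(elapsed, 60)
  expect_s3_class(study, "clinic_study")
  expect_true(file.exists(file.path(d1, "scenario_base", "summary.json")))
  expect_true(file.exists(file.path(d1, "scenario_3", "summary.json")))
  expect_true(file.exists(file.path(d1, "overall_tt_change.csv")))
  expect_true(file.exists(file.path(d1, "hourly_crowd_change.csv")))
  expect_true(file.exists(file.path(d1, "manifest.json")))
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_identical(man$master_seed, 3L)
  expect_identical(man$config_digest, config_digest(cfg))

  # identical seed and config => bit-identical summaries
  d2 <- withr::local_tempdir()
  run_full_study(cfg, out_dir = d2, master_seed = 3, n_replications = 2,
                 days = 1, scenarios = "3", quiet = TRUE)
  for (f in c("scenario_base/summary.json", "scenario_3/summary.json",
              "overall_tt_change.csv", "hourly_crowd_change.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
})

test_that("an uncalibrated study without calibration permission names the remedy", {
  cfg <- clinic_config(transfer = 9)
  expect_error(run_full_study(cfg, calibrate = FALSE, quiet = TRUE),
               "calibrate")
})

test_that("replication-set outputs export per-patient and per-hour CSVs", {
  set <- run_experiment("base", clinic_config(general_daily = 25L),
                        n_replications = 2, days = 1, master_seed = 8)
  d <- withr::local_tempdir()
  write_replication_set(set, d)
  tt <- read.csv(file.path(d, "turnaround_times.csv"))
  expect_identical(nrow(tt), nrow(set$tt))
  crowd <- read.csv(file.path(d, "hourly_crowd.csv"), check.names = FALSE)
  expect_identical(nrow(crowd), 10L)
  js <- jsonlite::read_json(file.path(d, "summary.json"))
  expect_identical(js$scenario, "base")
  # pooled summaries keep their names through JSON (the CLI compare verb
  # navigates summary.json by name)
  expect_equal(js$pooled$PUBLIC$median$overall_tt,
               unname(set$summary$pooled$PUBLIC["median", "overall_tt"]))
})

test_that("calibration returns the initial configuration when targets are already met", {
  # tiny-scale surrogate targets measured at the initial configuration make
  # the identity property checkable cheaply
  cfg <- clinic_config(general_daily = 40L)
  m <- evaluate_base_case(cfg, n_replications = 2, days = 1, master_seed = 6)
  cal <- calibrate_clinic(cfg, targets = m[c("reg_obs", "clin_obs")],
                          tolerance = 0.10, n_replications = 2, days = 1,
                          master_seed = 6)
  expect_true(cal$converged)
  expect_identical(cal$n_eval, 1L)
  expect_equal(cal$config$service, cfg$service)
  expect_equal(cal$config$transfer, cfg$transfer)
})

test_that("1-D calibration agrees with a brute-force grid on the same objective", {
  # single free parameter (QMS service median); the registration-TT target
  # responds monotonically, so the coordinate search must land within one
  # grid factor of the exhaustive optimum
  cfg <- clinic_config(general_daily = 120L)
  target <- c(reg_obs = 30)
  obj <- function(f) {
    c2 <- cfg
    c2$service$QMS <- lapply(c2$service$QMS, function(q) q * f)
    m <- evaluate_base_case(c2, n_replications = 2, days = 1, master_seed = 5)
    abs(m["reg_obs"] - target) / target
  }
  grid <- c(0.49, 0.7, 0.85, 1, 1.15, 1.4, 1.96)
  errs <- vapply(grid, obj, 0)
  best_grid <- grid[which.min(errs)]
  cal <- suppressWarnings(
    calibrate_clinic(cfg, targets = target, tolerance = 0.02,
                     budget = 12, free = "qms_median",
                     n_replications = 2, days = 1, master_seed = 5))
  achieved_factor <- cal$config$service$QMS$OBS[2] / cfg$service$QMS$OBS[2]
  # the search explores products of {0.7, 0.85, 1.15, 1.4}: it must end at
  # least as close to the target as the best single grid factor
  expect_lte(min(cal$trace[, "max_err"]), min(errs) + 1e-9)
  expect_true(abs(log(achieved_factor / best_grid)) < log(1.45) + 1e-9)
})
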