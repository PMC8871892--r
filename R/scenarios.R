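#' Scenario configurations
#'
#' Returns one of the study's eight operating configurations: the base case
#' (uncontrolled "block" arrival, consultations from ~09:00, private
#' registration from 11:30) or one of seven alternatives varying the arrival
#' pattern (even/staggered per 30-minute slot), the public registration start,
#' the consultation start, the per-slot arrival caps, the last public slot,
#' and the private patients' start time. Consultation-room downtime (atypical
#' consultations and inactive rooms) is part of the base case only; every
#' alternative scenario assumes it away.
#'
#' @param id `"base"` or an integer 1-7 (also accepts `"1"` ... `"7"`).
#' @return an object of class `"scenario_config"` with fields `id`,
#'   `arrival_pattern` (`"random"` or `"even"`), `qms_open`, `consult_start`,
#'   `public_slot_cap`, `last_public_slot`, `private_open`,
#'   `private_slot_cap`, `downtime_enabled` (clocks in minutes after
#'   midnight).
#' @examples
#' make_scenario(3)$public_slot_cap  # 10
#' make_scenario("base")$arrival_pattern
#' @export
make_scenario <- function(id) {
  key <- tolower(as.character(id))
  tab <- list(
    base = list(arrival_pattern = "random", qms_open = "07:00",
                consult_start = "09:00", public_slot_cap = 22,
                last_public_slot = "12:00", private_open = "11:30",
                private_slot_cap = 9, downtime_enabled = TRUE),
    `1` = list(arrival_pattern = "even", qms_open = "07:00",
               consult_start = "09:00", public_slot_cap = 22,
               last_public_slot = "12:00", private_open = "11:30",
               private_slot_cap = 9, downtime_enabled = FALSE),
    `2` = list(arrival_pattern = "even", qms_open = "07:00",
               consult_start = "08:15", public_slot_cap = 22,
               last_public_slot = "12:00", private_open = "11:30",
               private_slot_cap = 9, downtime_enabled = FALSE),
    `3` = list(arrival_pattern = "even", qms_open = "07:30",
               consult_start = "08:15", public_slot_cap = 10,
               last_public_slot = "12:00", private_open = "13:30",
               private_slot_cap = 2, downtime_enabled = FALSE),
    `4` = list(arrival_pattern = "even", qms_open = "07:30",
               consult_start = "09:00", public_slot_cap = 10,
               last_public_slot = "12:00", private_open = "13:30",
               private_slot_cap = 2, downtime_enabled = FALSE),
    `5` = list(arrival_pattern = "even", qms_open = "08:00",
               consult_start = "09:00", public_slot_cap = 7,
               last_public_slot = "15:00", private_open = "11:30",
               private_slot_cap = 9, downtime_enabled = FALSE),
    `6` = list(arrival_pattern = "even", qms_open = "08:00",
               consult_start = "09:00", public_slot_cap = 10,
               last_public_slot = "12:30", private_open = "13:30",
               private_slot_cap = 2, downtime_enabled = FALSE),
    `7` = list(arrival_pattern = "even", qms_open = "08:00",
               consult_start = "09:00", public_slot_cap = 10,
               last_public_slot = "12:30", private_open = "11:00",
               private_slot_cap = 2, downtime_enabled = FALSE))
  if (!key %in% names(tab)) stop("unknown scenario id: ", id)
  row <- tab[[key]]
  for (f in c("qms_open", "consult_start", "last_public_slot", "private_open"))
    row[[f]] <- hm(row[[f]])
  structure(c(list(id = key), row), class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "<scenario_config> %s: %s arrivals, QMS %s, consult %s, cap %d (last slot %s), private %s cap %d%s\n",
    x$id, x$arrival_pattern, fmt_clock(x$qms_open), fmt_clock(x$consult_start),
    x$public_slot_cap, fmt_clock(x$last_public_slot),
    fmt_clock(x$private_open), x$private_slot_cap,
    if (x$downtime_enabled) ", downtime on" else ""))
  invisible(x)
}

#' All scenario ids
#' @return character vector `c("base", "1", ..., "7")`.
#' @export
scenario_ids <- function() c("base", as.character(1:7))
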