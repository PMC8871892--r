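# Configuration file I/O. YAML is the native format; JSON is accepted.
# Clock fields may be written either as "HH:MM" strings or minutes after
# midnight; durations are always minutes.

#' Read a clinic configuration file
#'
#' Reads a YAML (or JSON) file of [clinic_config()] overrides. Any field may
#' be omitted — defaults fill the gaps. Clock fields (`general_open`,
#' `counters_close`, `private_session_earliest`, ...) accept `"HH:MM"`
#' strings.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return a [clinic_config()].
#' @export
read_clinic_config <- function(path) {
  lst <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  clock_fields <- c("general_open", "general_last_slot", "counters_close",
                    "clinic_open", "clinic_close", "consult_close",
                    "private_session_earliest")
  for (f in intersect(names(lst), clock_fields)) lst[[f]] <- hm(lst[[f]])
  for (f in intersect(names(lst), c("capacity")))
    lst[[f]] <- unlist(lst[[f]])
  if ("service" %in% names(lst))
    lst$service <- lapply(lst$service, function(by_class)
      lapply(by_class, as.numeric))
  if ("transfer" %in% names(lst)) lst$transfer <- unlist(lst$transfer)
  if ("rates" %in% names(lst)) lst$rates <- do.call(attribute_rates, lst$rates)
  do.call(clinic_config, lst)
}

#' Write a clinic configuration file
#'
#' Serialises a configuration (all fields, including defaults) as YAML.
#'
#' @param config a [clinic_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinic_config <- function(config, path) {
  stopifnot(inherits(config, "clinic_config"))
  out <- unclass(config)
  out$capacity <- as.list(out$capacity)
  out$rates <- out$rates[setdiff(names(out$rates), character(0))]
  yaml::write_yaml(out, path, precision = 12)
  invisible(path)
}

#' Build a scenario configuration from a list
#'
#' Accepts arbitrary scenario configurations beyond the eight published rows
#' (e.g. read from a YAML file): a named list with the fields of
#' [make_scenario()]'s return value.
#'
#' @param x a named list with `id`, `arrival_pattern`, `qms_open`,
#'   `consult_start`, `public_slot_cap`, `last_public_slot`, `private_open`,
#'   `private_slot_cap`, and optionally `downtime_enabled` (default
#'   `FALSE`); clocks as `"HH:MM"` or minutes.
#' @return a `"scenario_config"`.
#' @export
as_scenario_config <- function(x) {
  need <- c("id", "arrival_pattern", "qms_open", "consult_start",
            "public_slot_cap", "last_public_slot", "private_open",
            "private_slot_cap")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("scenario config lacks fields: ", paste(missing, collapse = ", "))
  if (!x$arrival_pattern %in% c("random", "even"))
    stop("arrival_pattern must be 'random' or 'even'")
  sc <- list(id = as.character(x$id), arrival_pattern = x$arrival_pattern,
             qms_open = hm(x$qms_open), consult_start = hm(x$consult_start),
             public_slot_cap = as.integer(x$public_slot_cap),
             last_public_slot = hm(x$last_public_slot),
             private_open = hm(x$private_open),
             private_slot_cap = as.integer(x$private_slot_cap),
             downtime_enabled = isTRUE(x$downtime_enabled))
  if (sc$last_public_slot < sc$qms_open)
    stop("last_public_slot must not precede qms_open")
  structure(sc, class = "scenario_config")
}
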