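# The clinic model: stations, staff, routing and entity generation for the
# dual-practice O&G outpatient clinic.
#
# Patient flow (public):  QMS -> REVENUE -> OG_COUNTER -> VITALS -> [LAB] ->
#   CONSULT (doctor; + specialist discussion for ~10% of cases) -> NURSES ->
#   exit.
# Patient flow (private): PRIVATE_COUNTER (registration) -> VITALS -> [LAB]
#   -> CONSULT_PRIV (private specialist only) -> PRIVATE_COUNTER (payment &
#   appointment) -> exit.
# General (non-O&G) patients load only the shared QMS and revenue counters:
#   QMS -> REVENUE -> exit.

.clinic_station_names <- c("QMS", "REVENUE", "OG_COUNTER", "VITALS", "LAB",
                           "CONSULT", "SPECIALIST", "NURSES",
                           "PRIVATE_COUNTER", "CONSULT_PRIV")

.stn <- function(name) match(name, .clinic_station_names)

#' Default clinic configuration
#'
#' All operational parameters of the clinic model, with defaults encoding the
#' study clinic: ten consultation rooms staffed by seven doctors and three
#' specialists (all ten may see public patients concurrently, capped by the
#' rooms), two private specialists, two vital-sign stations, two nurses'
#' stations, one O&G registration counter, one private counter, a laboratory,
#' and the shared outpatient front end (QMS and revenue counters). Process
#' times at clinic stations are the published median/quartile triples
#' (minutes); front-end service times, inter-station transfer time and the
#' base-case downtime process are calibrated quantities (see
#' [calibrate_clinic()]) whose shipped defaults already satisfy the published
#' turnaround-time targets.
#'
#' @param ... named overrides of any default listed below.
#' @return an object of class `"clinic_config"` (a named list).
#' @section Main fields:
#' * `public_daily`, `private_daily`, `general_daily` — daily volumes
#'   (86 / 7 / 867; general = 4802 total patients over the 5 observed days
#'   minus the O&G patients, i.e. the load the other five specialist clinics
#'   put on the shared counters);
#' * `service` — per-station, per-class `(q1, median, q3)` triples;
#' * `capacity` — servers per station;
#' * `transfer` — constant walking time between stations (minutes);
#' * `downtime_*` — base-case room-blocking episodes;
#' * `rates` — attribute probabilities ([attribute_rates()]);
#' * `public_block_weights` — per-slot weights of the uncontrolled public
#'   arrival pattern (NULL = morning-peak default, [peak_weights()]).
#' @export
clinic_config <- function(...) {
  cfg <- list(
    public_daily = 86L,
    private_daily = 7L,
    general_daily = 867L,
    capacity = c(QMS = 2L, REVENUE = 4L, OG_COUNTER = 1L, VITALS = 2L,
                 LAB = 2L, CONSULT = 10L, SPECIALIST = 3L, NURSES = 2L,
                 PRIVATE_COUNTER = 1L, CONSULT_PRIV = 2L),
    doctors = 7L, specialists = 3L, private_specialists = 2L, rooms = 10L,
    service = list(
      QMS = list(OBS = c(0.32, 0.52, 0.91), GYN = c(0.32, 0.52, 0.91),
                 GENERAL = c(0.32, 0.52, 0.91)),
      REVENUE = list(OBS = c(0.57, 0.92, 1.61), GYN = c(0.57, 0.92, 1.61),
                     GENERAL = c(0.57, 0.92, 1.61)),
      OG_COUNTER = list(OBS = c(0.5, 1, 2), GYN = c(0.5, 1, 2)),
      VITALS = list(OBS = c(1, 2, 3), GYN = c(1, 2, 4), PRIVATE = c(1, 1, 1)),
      LAB = list(OBS = c(3, 4, 6), GYN = c(3, 4, 6), PRIVATE = c(2, 3, 4)),
      CONSULT = list(OBS = c(10, 13, 20), GYN = c(7, 10, 17)),
      SPECIALIST = list(OBS = c(3, 5, 8), GYN = c(3, 5, 8)),
      NURSES = list(OBS = c(1, 2, 4), GYN = c(1, 2, 4)),
      PRIVATE_COUNTER = list(PRIVATE = c(2, 4, 7)),
      CONSULT_PRIV = list(PRIVATE = c(13, 17, 21))),
    transfer = 2,
    public_consult_capacity = 7L,
    # per-consultation EMR review + documentation time (expert estimate,
    # never observed in the published process times): occupies the doctor
    # and room on top of the face-to-face consultation draw
    emr_overhead = c(4, 7, 11),
    private_session_earliest = hm("12:30"),
    downtime_episodes_per_day = 2L,
    downtime_duration = c(15, 45),
    downtime_window = c(hm("09:00"), hm("12:00")),
    rates = attribute_rates(),
    public_block_weights = NULL,
    general_open = hm("07:00"), general_last_slot = hm("15:30"),
    counters_close = hm("17:30"),
    clinic_open = hm("07:30"), clinic_close = hm("17:00"),
    consult_close = hm("13:00"),
    lunch_minutes = 60,
    private_slots = 4L,
    calibrated = TRUE)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown clinic_config fields: ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  # overriding a calibration-sensitive parameter invalidates the shipped
  # calibration unless the caller asserts otherwise
  sensitive <- c("service", "emr_overhead", "transfer", "downtime_duration",
                 "downtime_episodes_per_day", "private_session_earliest",
                 "public_consult_capacity")
  if (!"calibrated" %in% names(over) && any(names(over) %in% sensitive))
    cfg$calibrated <- FALSE
  structure(cfg, class = "clinic_config")
}

#' @export
print.clinic_config <- function(x, ...) {
  cat("<clinic_config>\n")
  cat(sprintf("  daily volumes: %d public + %d private O&G, %d general\n",
              x$public_daily, x$private_daily, x$general_daily))
  cat(sprintf("  consult capacity %d (doctors %d + specialists %d, rooms %d); private specialists %d\n",
              x$capacity[["CONSULT"]], x$doctors, x$specialists, x$rooms,
              x$private_specialists))
  cat(sprintf("  transfer %g min; downtime %d x U(%g,%g) min/day (base case only)\n",
              x$transfer, x$downtime_episodes_per_day,
              x$downtime_duration[1], x$downtime_duration[2]))
  invisible(x)
}

# config$transfer may be a scalar, or a named vector giving the walking/
# in-between time by destination station (unnamed stations keep the scalar
# default of 2).
.transfer_vector <- function(cfg) {
  tr <- cfg$transfer
  ns <- length(.clinic_station_names)
  if (is.null(names(tr))) return(rep(as.numeric(tr[1]), ns))
  out <- rep(2, ns)
  hit <- match(names(tr), .clinic_station_names)
  if (anyNA(hit)) stop("unknown station in transfer: ",
                       paste(names(tr)[is.na(hit)], collapse = ", "))
  out[hit] <- as.numeric(tr)
  out
}

# Fitted service_dist table, computed once per model build.
.fit_service_table <- function(cfg) {
  lapply(cfg$service, function(by_class)
    lapply(by_class, function(q) fit_quantile_dist(quantile_spec(q[1], q[2], q[3]))))
}

#' Station route for one patient
#'
#' The sequence of stations a patient visits, by class and attributes.
#'
#' @param class `"OBS"`, `"GYN"`, `"PRIVATE"` or `"GENERAL"`.
#' @param needs_lab logical.
#' @return character vector of station names.
#' @examples
#' patient_route("OBS", needs_lab = TRUE)
#' patient_route("PRIVATE", needs_lab = FALSE)
#' @export
patient_route <- function(class, needs_lab = FALSE) {
  switch(class,
    GENERAL = c("QMS", "REVENUE"),
    OBS = ,
    GYN = c("QMS", "REVENUE", "OG_COUNTER", "VITALS",
            if (needs_lab) "LAB", "CONSULT", "NURSES"),
    PRIVATE = c("PRIVATE_COUNTER", "VITALS", if (needs_lab) "LAB",
                "CONSULT_PRIV", "PRIVATE_COUNTER"),
    stop("unknown patient class: ", class))
}

# Private consultation session: the specialists' one-hour lunch ends 30 min
# after the private counter opens, but the session can never start before the
# configured earliest switch-over from public duty (dual practice: private
# service follows public service).
private_consult_start <- function(scenario, cfg) {
  max(scenario$private_open + cfg$lunch_minutes - 30,
      cfg$private_session_earliest)
}

#' Build the clinic simulation model for one scenario
#'
#' Assembles stations (capacities, daily opening windows, work-to-finish
#' flags) and fitted service-time distributions for a scenario. Doctors and
#' specialists work-to-finish (they keep serving the queue past the session
#' close); registration counters stop admitting at their close time.
#'
#' @param config a [clinic_config()].
#' @param scenario a [make_scenario()] configuration.
#' @param days clinic days per replication.
#' @return an object of class `"clinic_model"`.
#' @export
build_clinic <- function(config = clinic_config(), scenario = make_scenario("base"),
                         days = 5) {
  stopifnot(inherits(config, "clinic_config"),
            inherits(scenario, "scenario_config"))
  for (st in .clinic_station_names[c(1:6, 8:10)]) {
    classes <- switch(st,
      QMS = , REVENUE = c("OBS", "GYN", "GENERAL"),
      OG_COUNTER = , CONSULT = , NURSES = c("OBS", "GYN"),
      VITALS = c("OBS", "GYN", "PRIVATE"),
      LAB = c("OBS", "PRIVATE"),
      PRIVATE_COUNTER = , CONSULT_PRIV = "PRIVATE")
    missing <- setdiff(classes, names(config$service[[st]]))
    if (length(missing))
      stop(sprintf("missing service distribution for (%s, %s)",
                   st, paste(missing, collapse = "/")))
  }
  priv_consult_open <- private_consult_start(scenario, config)
  w <- function(open, close) daily_windows(open, close, days)
  stations <- list(
    des_station("QMS", config$capacity[["QMS"]],
                w(min(hm("07:00"), scenario$qms_open), config$counters_close),
                work_to_finish = FALSE),
    des_station("REVENUE", config$capacity[["REVENUE"]],
                w(min(hm("07:00"), scenario$qms_open), config$counters_close),
                work_to_finish = FALSE),
    des_station("OG_COUNTER", config$capacity[["OG_COUNTER"]],
                w(config$clinic_open, config$counters_close),
                work_to_finish = FALSE),
    des_station("VITALS", config$capacity[["VITALS"]],
                w(config$clinic_open, config$clinic_close)),
    des_station("LAB", config$capacity[["LAB"]],
                w(config$clinic_open, config$clinic_close)),
    des_station("CONSULT",
                min(config$rooms, config$public_consult_capacity),
                w(scenario$consult_start, config$consult_close),
                random_assign = TRUE),
    des_station("SPECIALIST", config$specialists,
                w(scenario$consult_start, config$consult_close)),
    des_station("NURSES", config$capacity[["NURSES"]],
                w(config$clinic_open, config$clinic_close)),
    des_station("PRIVATE_COUNTER", config$capacity[["PRIVATE_COUNTER"]],
                w(scenario$private_open, config$counters_close),
                work_to_finish = FALSE),
    des_station("CONSULT_PRIV", config$private_specialists,
                w(priv_consult_open, config$clinic_close)))
  structure(list(config = config, scenario = scenario, days = days,
                 stations = stations, dists = .fit_service_table(config),
                 overhead_dist = fit_quantile_dist(
                   quantile_spec(config$emr_overhead[1], config$emr_overhead[2],
                                 config$emr_overhead[3]))),
            class = "clinic_model")
}

#' @export
print.clinic_model <- function(x, ...) {
  cat(sprintf("<clinic_model> scenario %s, %d day(s)/replication\n",
              x$scenario$id, x$days))
  print(x$scenario)
  invisible(x)
}

# Arrival schedules realised for one scenario.
.clinic_schedules <- function(cfg, sc) {
  pattern <- if (sc$arrival_pattern == "random") "block_random" else "even_staggered"
  n_pub_slots <- (sc$last_public_slot - sc$qms_open) %/% 30 + 1
  pub_w <- if (pattern == "block_random") {
    if (is.null(cfg$public_block_weights)) peak_weights(n_pub_slots, sc$qms_open)
    else cfg$public_block_weights
  } else NULL
  priv_last <- sc$private_open + 30 * (cfg$private_slots - 1)
  priv_w <- if (pattern == "block_random") c(0.4, 0.3, 0.2, 0.1)[seq_len(cfg$private_slots)]
  list(
    public = arrival_schedule(pattern, sc$qms_open, sc$last_public_slot,
                              sc$public_slot_cap, cfg$public_daily, "PUBLIC",
                              weights = pub_w),
    private = arrival_schedule(pattern, sc$private_open, priv_last,
                               sc$private_slot_cap, cfg$private_daily,
                               "PRIVATE", weights = priv_w),
    # the other five clinics' patients are outside the scenario levers:
    # always the uncontrolled morning-peak pattern
    general = arrival_schedule("block_random", cfg$general_open,
                               cfg$general_last_slot, Inf, cfg$general_daily,
                               "GENERAL"))
}

# Draw service times for patients at one station, aligned by patient order
# within (station, class) so scenarios sharing a master seed share draws.
.draw_services <- function(dist, n, seed) {
  if (n == 0) return(numeric(0))
  simulate(dist, nsim = n, seed = seed)
}

#' Simulate one replication of the clinic
#'
#' Generates seeded arrivals, attributes and service draws for `days`
#' consecutive clinic days, runs the event engine, and returns the complete
#' log with the patient table. Every stochastic element consumes a named
#' substream derived from `(master_seed, rep)`, so scenarios sharing a master
#' seed use common random numbers (see [substream_seed()]).
#'
#' @param model a [build_clinic()] model.
#' @param rep replication index (>= 1).
#' @param master_seed integer master seed.
#' @param record_events keep the full event record (default `FALSE`; the
#'   per-entity trail, which all metrics use, is always kept).
#' @return an object of class `"clinic_run"`: `log` (a `"des_log"`),
#'   `patients` (one row per entity: class, day, attributes, arrival),
#'   `scenario`, `days`, `rep`.
#' @export
simulate_replication <- function(model, rep = 1, master_seed = 1,
                                 record_events = FALSE) {
  stopifnot(inherits(model, "clinic_model"))
  cfg <- model$config; sc <- model$scenario; days <- model$days
  sch <- .clinic_schedules(cfg, sc)
  seed_of <- function(name) substream_seed(master_seed, rep, name)

  pub <- generate_arrivals(sch$public, days, seed_of("arrivals/public"))
  priv <- generate_arrivals(sch$private, days, seed_of("arrivals/private"))
  gen <- generate_arrivals(sch$general, days, seed_of("arrivals/general"))

  pub_at <- assign_attributes("PUBLIC", nrow(pub), cfg$rates,
                              seed_of("attributes/public"))
  priv_at <- assign_attributes("PRIVATE", nrow(priv), cfg$rates,
                               seed_of("attributes/private"))

  patients <- rbind(
    data.frame(class = pub_at$class, day = pub$day, time = pub$time,
               abs_time = pub$abs_time, k = pub$k,
               age_group = pub_at$age_group,
               appointment_type = pub_at$appointment_type,
               needs_lab = pub_at$needs_lab,
               needs_specialist = pub_at$needs_specialist),
    data.frame(class = priv_at$class, day = priv$day, time = priv$time,
               abs_time = priv$abs_time, k = priv$k,
               age_group = priv_at$age_group,
               appointment_type = priv_at$appointment_type,
               needs_lab = priv_at$needs_lab,
               needs_specialist = priv_at$needs_specialist),
    if (nrow(gen)) data.frame(class = "GENERAL", day = gen$day,
                              time = gen$time, abs_time = gen$abs_time,
                              k = gen$k, age_group = "non_elderly",
                              appointment_type = "follow_up",
                              needs_lab = FALSE, needs_specialist = FALSE))

  # base-case downtime: room-blocking episodes entering the consultation
  # queue like entities
  if (sc$downtime_enabled && cfg$downtime_episodes_per_day > 0) {
    dt <- with_seed(seed_of("downtime"), {
      nepi <- cfg$downtime_episodes_per_day * days
      data.frame(
        day = rep(seq_len(days), each = cfg$downtime_episodes_per_day),
        at = stats::runif(nepi, cfg$downtime_window[1], cfg$downtime_window[2]),
        dur = stats::runif(nepi, cfg$downtime_duration[1], cfg$downtime_duration[2]))
    })
    patients <- rbind(patients,
      data.frame(class = "BLOCKER", day = dt$day, time = dt$at,
                 abs_time = day_offset(dt$day) + dt$at, k = seq_len(nrow(dt)),
                 age_group = "non_elderly", appointment_type = "follow_up",
                 needs_lab = FALSE, needs_specialist = FALSE))
  }

  n <- nrow(patients)
  route_names <- vector("list", n)
  for (i in seq_len(n)) {
    route_names[[i]] <- if (patients$class[i] == "BLOCKER") "CONSULT"
      else patient_route(patients$class[i], patients$needs_lab[i])
  }
  route <- lapply(route_names, .stn)

  # service draws, one substream per (station, class), consumed in patient
  # order so draws align across scenarios with the same master seed
  service <- lapply(route_names, function(r) numeric(length(r)))
  for (st in names(model$dists)) {
    for (cl in names(model$dists[[st]])) {
      sel_class <- if (cl == "GENERAL") "GENERAL" else cl
      idx <- which(patients$class == sel_class &
                     vapply(route_names, function(r) st %in% r, TRUE))
      if (!length(idx)) next
      draws <- .draw_services(model$dists[[st]][[cl]], length(idx),
                              seed_of(paste0("service/", st, "/", cl)))
      for (j in seq_along(idx)) {
        i <- idx[j]
        pos <- which(route_names[[i]] == st)
        service[[i]][pos[1]] <- draws[j]
        if (length(pos) > 1)  # private counter: registration then payment
          service[[i]][pos[2]] <- draws[j]
      }
    }
  }
  # doctors' EMR review + documentation occupies the room on top of the
  # face-to-face consultation time
  pub_idx <- which(patients$class %in% c("OBS", "GYN"))
  if (length(pub_idx)) {
    oh <- .draw_services(model$overhead_dist, length(pub_idx),
                         seed_of("service/CONSULT/overhead"))
    for (j in seq_along(pub_idx)) {
      i <- pub_idx[j]
      pos <- which(route_names[[i]] == "CONSULT")
      service[[i]][pos] <- service[[i]][pos] + oh[j]
    }
  }
  # the private counter's two visits should not share one draw: redraw the
  # payment visit from its own substream
  pc_idx <- which(patients$class == "PRIVATE")
  if (length(pc_idx)) {
    pay <- .draw_services(model$dists$PRIVATE_COUNTER$PRIVATE, length(pc_idx),
                          seed_of("service/PRIVATE_COUNTER/PRIVATE/payment"))
    for (j in seq_along(pc_idx)) {
      i <- pc_idx[j]
      pos <- which(route_names[[i]] == "PRIVATE_COUNTER")
      service[[i]][pos[2]] <- pay[j]
    }
  }
  # blocker "service" is the episode duration
  blk <- which(patients$class == "BLOCKER")
  if (length(blk)) service[blk] <- as.list(dt$dur)

  # specialist discussions extend the consultation of flagged public patients
  ext_step <- rep(NA_integer_, n); ext_station <- rep(NA_integer_, n)
  ext_dur <- rep(NA_real_, n)
  flag <- which(patients$needs_specialist)
  if (length(flag)) {
    dd <- .draw_services(model$dists$SPECIALIST$OBS, length(flag),
                         seed_of("service/SPECIALIST/discussion"))
    for (j in seq_along(flag)) {
      i <- flag[j]
      ext_step[i] <- which(route_names[[i]] == "CONSULT")
      ext_station[i] <- .stn("SPECIALIST")
      ext_dur[i] <- dd[j]
    }
  }

  m <- des_model(model$stations, patients$abs_time, route, service,
                 ext_step, ext_station, ext_dur,
                 transfer = .transfer_vector(cfg))
  log <- des_run(m, assign_seed = seed_of("assign"),
                 record_events = record_events)
  structure(list(log = log, patients = patients, scenario = sc,
                 days = days, rep = rep, master_seed = master_seed,
                 station_names = .clinic_station_names),
            class = "clinic_run")
}

#' @export
print.clinic_run <- function(x, ...) {
  og <- x$patients$class %in% c("OBS", "GYN", "PRIVATE")
  cat(sprintf(
    "<clinic_run> scenario %s, rep %d, %d day(s): %d O&G patients (+%d general)\n",
    x$scenario$id, x$rep, x$days, sum(og), sum(x$patients$class == "GENERAL")))
  invisible(x)
}
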