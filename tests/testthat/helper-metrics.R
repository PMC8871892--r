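# Hand-built clinic_run objects and a brute-force crowd recount, used as
# independent oracles for the metrics module.

# Build a minimal clinic_run from explicit timestamps. `spec` is a data
# frame with one row per patient: class, arrival, reg_end (O&G or private
# counter registration completion), departure, and optionally a list-column
# `service` of (start, end) in-service intervals after registration.
fake_clinic_run <- function(spec, days = 1) {
  n <- nrow(spec)
  station_names <- c("QMS", "REVENUE", "OG_COUNTER", "VITALS", "LAB",
                     "CONSULT", "SPECIALIST", "NURSES", "PRIVATE_COUNTER",
                     "CONSULT_PRIV")
  trail <- list()
  for (i in seq_len(n)) {
    reg_station <- if (spec$class[i] == "PRIVATE") 9L else 3L
    trail[[length(trail) + 1]] <- data.frame(
      entity = i, step = 1L, station = reg_station,
      t_join = spec$arrival[i], t_start = spec$arrival[i],
      t_end = spec$reg_end[i], server = 1L)
    if (!is.null(spec$service)) {
      ivs <- spec$service[[i]]
      if (length(ivs)) for (k in seq_along(ivs)) {
        trail[[length(trail) + 1]] <- data.frame(
          entity = i, step = 1L + k, station = 6L,
          t_join = ivs[[k]][1], t_start = ivs[[k]][1], t_end = ivs[[k]][2],
          server = 1L)
      }
    }
  }
  trail <- if (length(trail)) do.call(rbind, trail)
    else data.frame(entity = integer(), step = integer(),
                    station = integer(), t_join = numeric(),
                    t_start = numeric(), t_end = numeric(),
                    server = integer())
  structure(list(
    log = list(trail = trail, arrival = spec$arrival,
               departure = spec$departure),
    patients = data.frame(class = spec$class, day = rep(1L, n),
                          time = spec$arrival %% 1440,
                          abs_time = spec$arrival,
                          k = seq_len(n),
                          age_group = rep("non_elderly", n),
                          appointment_type = rep("follow_up", n),
                          needs_lab = rep(FALSE, n),
                          needs_specialist = rep(FALSE, n)),
    scenario = make_scenario("base"), days = days, rep = 1L,
    master_seed = 0L, station_names = station_names),
    class = "clinic_run")
}

# independent per-minute membership recount
crowd_recount <- function(spec, hours = 7:16, days = 1) {
  out <- numeric(length(hours))
  for (hi in seq_along(hours)) {
    total <- 0
    for (d in seq_len(days)) {
      for (m in (hours[hi] * 60):(hours[hi] * 60 + 59)) {
        t <- 1440 * (d - 1) + m
        for (i in seq_len(nrow(spec))) {
          present <- spec$reg_end[i] <= t && t < spec$departure[i]
          if (present && !is.null(spec$service)) {
            for (iv in spec$service[[i]])
              if (iv[1] <= t && t < iv[2]) present <- FALSE
          }
          total <- total + present
        }
      }
    }
    out[hi] <- total / 60 / days
  }
  names(out) <- sprintf("%02d:00", hours)
  out
}
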