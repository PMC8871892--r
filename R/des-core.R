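# Event-calendar discrete-event simulation engine.
#
# The engine is generic: stations with integer capacity and opening windows,
# FIFO queues, optional "work-to-finish" semantics (a resource keeps starting
# queued services after its closing time, as clinic doctors do), optional
# uniformly-random assignment among free servers, and an optional secondary
# ("extension") resource that an entity seizes at the end of its base service
# while still holding the primary one (used for specialist discussions that
# extend a consultation). Events are processed in non-decreasing time order
# with ties broken by insertion sequence, so a run is fully deterministic
# given its inputs.

#' Define a station (capacity-constrained resource)
#'
#' @param name station name (unique within a model).
#' @param capacity integer number of parallel servers (>= 1).
#' @param windows numeric matrix with columns `open`, `close`: absolute
#'   simulation minutes during which services may start. Use
#'   [daily_windows()] to repeat a clock window over consecutive days.
#' @param work_to_finish logical; if `TRUE` the station keeps starting queued
#'   services after `close` (it stops only when its queue is empty), if
#'   `FALSE` no service starts outside an open window.
#' @param random_assign logical; if `TRUE` each service start picks uniformly
#'   at random among the free servers (doctor assignment), otherwise the
#'   lowest-numbered free server is used.
#' @return an object of class `"des_station"`.
#' @export
des_station <- function(name, capacity, windows = matrix(c(0, Inf), 1),
                        work_to_finish = TRUE, random_assign = FALSE) {
  if (capacity < 1 || capacity != round(capacity))
    stop("capacity must be a positive integer")
  windows <- matrix(as.numeric(windows), ncol = 2)
  if (any(windows[, 1] > windows[, 2])) stop("window open must precede close")
  windows <- windows[order(windows[, 1]), , drop = FALSE]
  structure(list(name = name, capacity = as.integer(capacity),
                 windows = windows, work_to_finish = isTRUE(work_to_finish),
                 random_assign = isTRUE(random_assign)),
            class = "des_station")
}

#' Repeat a daily clock window over consecutive days
#'
#' @param open,close clock times (`"HH:MM"` or minutes after midnight).
#' @param days number of consecutive days.
#' @return a windows matrix suitable for [des_station()].
#' @export
daily_windows <- function(open, close, days = 1) {
  open <- hm(open); close <- hm(close)
  d <- day_offset(seq_len(days))
  cbind(open + d, close + d)
}

#' Assemble a simulation model for [des_run()]
#'
#' `entities` are described up front: each has an arrival time, a route
#' (station indices visited in order, each with a pre-drawn service time),
#' and optionally one extension — a secondary resource seized at the end of
#' the base service of one route step and held, together with the primary
#' station's server, for an extra duration.
#'
#' @param stations list of [des_station()] objects.
#' @param arrival numeric vector of entity arrival times (absolute minutes).
#' @param route list of integer vectors: station indices per entity.
#' @param service list of numeric vectors, same shapes as `route`:
#'   service times in minutes (must be non-negative).
#' @param ext_step,ext_station,ext_dur optional per-entity extension: route
#'   step at which it applies (`NA` for none), station index of the
#'   secondary resource, and its duration.
#' @param transfer transfer (walking) time added between consecutive
#'   stations of a route: a scalar, or a vector with one entry per station
#'   (the transfer time then depends on the destination).
#' @return an object of class `"des_model"`.
#' @export
des_model <- function(stations, arrival, route, service,
                      ext_step = NULL, ext_station = NULL, ext_dur = NULL,
                      transfer = 0) {
  ns <- length(stations)
  if (ns < 1) stop("model needs at least one station")
  stopifnot(all(vapply(stations, inherits, TRUE, "des_station")))
  n <- length(arrival)
  if (length(route) != n || length(service) != n)
    stop("route and service must have one element per entity")
  if (n) {
    rl <- vapply(route, length, 1L)
    if (any(rl < 1)) stop("every entity needs an entry station")
    if (!identical(rl, vapply(service, length, 1L)))
      stop("service times must match route lengths")
    allst <- unlist(route, use.names = FALSE)
    if (any(allst < 1 | allst > ns))
      stop("entity routed to unknown station")
    if (any(unlist(service, use.names = FALSE) < 0))
      stop("service times must be non-negative")
  }
  if (is.null(ext_step)) ext_step <- rep(NA_integer_, n)
  if (is.null(ext_station)) ext_station <- rep(NA_integer_, n)
  if (is.null(ext_dur)) ext_dur <- rep(NA_real_, n)
  has_ext <- !is.na(ext_step)
  if (any(has_ext)) {
    if (any(ext_station[has_ext] < 1 | ext_station[has_ext] > ns))
      stop("extension routed to unknown station")
    if (any(ext_dur[has_ext] < 0))
      stop("extension durations must be non-negative")
  }
  if (!length(transfer) %in% c(1L, ns))
    stop("transfer must be a scalar or one value per station")
  if (any(transfer < 0)) stop("transfer times must be non-negative")
  structure(list(stations = stations, arrival = as.numeric(arrival),
                 route = lapply(route, as.integer),
                 service = lapply(service, as.numeric),
                 ext_step = as.integer(ext_step),
                 ext_station = as.integer(ext_station),
                 ext_dur = as.numeric(ext_dur),
                 transfer = as.numeric(transfer)),
            class = "des_model")
}

.event_kinds <- c("arrival", "service_start", "service_end", "transfer",
                  "departure", "resource_open")

#' Run a discrete-event simulation
#'
#' Processes the event calendar until it is empty (or `horizon` is reached):
#' entities arrive at their first station, queue FIFO, seize a free server
#' when the station is open (or, for work-to-finish stations, any time after
#' opening), and move through their route after each service completes. An
#' entity with an extension seizes the secondary resource at the end of the
#' flagged step's base service, holding the primary server throughout; both
#' are released together.
#'
#' @param model a [des_model()].
#' @param horizon stop processing events after this time (default `Inf`;
#'   entities still in the system at the horizon keep `NA` departures).
#' @param assign_seed integer seed for the engine's internal
#'   random-server-assignment stream (only consumed by stations with
#'   `random_assign = TRUE`; independent of R's global RNG).
#' @param record_events logical; keep the full ordered event record in
#'   addition to the per-entity trail.
#' @return an object of class `"des_log"` with elements `trail` (one row per
#'   entity-step: `entity`, `step`, `station`, `t_join`, `t_start`, `t_end`,
#'   `server`), `arrival`, `departure`, `ext` (extension join/start/end,
#'   `NA` when absent), `events` (data frame or `NULL`) and
#'   `station_names`.
#' @examples
#' st <- list(des_station("s", 1))
#' m <- des_model(st, arrival = c(0, 1, 2),
#'                route = list(1L, 1L, 1L), service = list(5, 5, 5))
#' des_run(m)$trail
#' @export
des_run <- function(model, horizon = Inf, assign_seed = 1L,
                    record_events = TRUE) {
  stopifnot(inherits(model, "des_model"))
  stations <- model$stations
  ns <- length(stations)
  n <- length(model$arrival)

  cap <- vapply(stations, `[[`, 1L, "capacity")
  wtf <- vapply(stations, `[[`, TRUE, "work_to_finish")
  rnd <- vapply(stations, `[[`, TRUE, "random_assign")
  wins <- lapply(stations, `[[`, "windows")

  rlen <- vapply(model$route, length, 1L)
  if (!n) rlen <- integer(0)
  off <- c(0L, cumsum(rlen))
  route_flat <- as.integer(unlist(model$route, use.names = FALSE))
  svc_flat <- as.numeric(unlist(model$service, use.names = FALSE))
  nrows <- length(route_flat)
  transfer <- if (length(model$transfer) == 1L) rep(model$transfer, ns)
              else model$transfer
  ext_step <- model$ext_step; ext_st <- model$ext_station
  ext_dur <- model$ext_dur

  t_join <- rep(NA_real_, nrows); t_start <- rep(NA_real_, nrows)
  t_end <- rep(NA_real_, nrows); srv_of <- rep(NA_integer_, nrows)
  departure <- rep(NA_real_, n)
  ext_join <- rep(NA_real_, n); ext_start_t <- rep(NA_real_, n)
  ext_end_t <- rep(NA_real_, n)

  cur <- rep(1L, n)           # current route step per entity
  stage <- rep(0L, n)         # 0 queue/travel, 1 in service, 2 ext wait, 3 in ext
  held_server <- rep(NA_integer_, n)
  ext_server <- rep(NA_integer_, n)

  busy <- integer(ns)
  free_srv <- lapply(cap, seq_len)
  qbuf <- lapply(rep(64L, ns), integer)
  qh <- integer(ns); qt <- integer(ns)
  wake_at <- rep(Inf, ns)

  # binary min-heap keyed by (time, insertion sequence)
  hcap <- 256L
  ht <- numeric(hcap); hq <- numeric(hcap)
  he <- integer(hcap); hst <- integer(hcap); hk <- integer(hcap)
  hn <- 0L; seqc <- 0
  push <- function(t, ent, st, kind) {
    hn <<- hn + 1L; seqc <<- seqc + 1
    if (hn > hcap) {
      grow <- hcap
      hcap <<- hcap * 2L
      ht <<- c(ht, numeric(grow)); hq <<- c(hq, numeric(grow))
      he <<- c(he, integer(grow)); hst <<- c(hst, integer(grow))
      hk <<- c(hk, integer(grow))
    }
    i <- hn
    ht[i] <<- t; hq[i] <<- seqc; he[i] <<- ent; hst[i] <<- st; hk[i] <<- kind
    while (i > 1L) {
      p <- i %/% 2L
      if (ht[p] > ht[i] || (ht[p] == ht[i] && hq[p] > hq[i])) {
        tt <- ht[p]; ht[p] <<- ht[i]; ht[i] <<- tt
        tt <- hq[p]; hq[p] <<- hq[i]; hq[i] <<- tt
        ti <- he[p]; he[p] <<- he[i]; he[i] <<- ti
        ti <- hst[p]; hst[p] <<- hst[i]; hst[i] <<- ti
        ti <- hk[p]; hk[p] <<- hk[i]; hk[i] <<- ti
        i <- p
      } else break
    }
  }
  pop <- function() {
    out <- c(ht[1L], he[1L], hst[1L], hk[1L])
    ht[1L] <<- ht[hn]; hq[1L] <<- hq[hn]; he[1L] <<- he[hn]
    hst[1L] <<- hst[hn]; hk[1L] <<- hk[hn]
    hn <<- hn - 1L
    i <- 1L
    repeat {
      l <- 2L * i; r <- l + 1L
      if (l > hn) break
      m <- l
      if (r <= hn && (ht[r] < ht[l] || (ht[r] == ht[l] && hq[r] < hq[l]))) m <- r
      if (ht[m] < ht[i] || (ht[m] == ht[i] && hq[m] < hq[i])) {
        tt <- ht[m]; ht[m] <<- ht[i]; ht[i] <<- tt
        tt <- hq[m]; hq[m] <<- hq[i]; hq[i] <<- tt
        ti <- he[m]; he[m] <<- he[i]; he[i] <<- ti
        ti <- hst[m]; hst[m] <<- hst[i]; hst[i] <<- ti
        ti <- hk[m]; hk[m] <<- hk[i]; hk[i] <<- ti
        i <- m
      } else break
    }
    out
  }

  ev_n <- 0L; ev_cap <- if (record_events) 1024L else 0L
  ev_t <- numeric(ev_cap); ev_k <- integer(ev_cap)
  ev_e <- integer(ev_cap); ev_s <- integer(ev_cap)
  note <- function(t, kind, ent, st) {
    ev_n <<- ev_n + 1L
    if (ev_n > ev_cap) {
      grow <- ev_cap
      ev_cap <<- ev_cap * 2L
      ev_t <<- c(ev_t, numeric(grow)); ev_k <<- c(ev_k, integer(grow))
      ev_e <<- c(ev_e, integer(grow)); ev_s <<- c(ev_s, integer(grow))
    }
    ev_t[ev_n] <<- t; ev_k[ev_n] <<- kind; ev_e[ev_n] <<- ent; ev_s[ev_n] <<- st
  }

  # minimal-standard LCG; keeps server assignment independent of R's RNG
  lcg_state <- as.numeric(assign_seed %% 2147483646 + 1)
  lcg <- function() {
    lcg_state <<- (lcg_state * 48271) %% 2147483647
    lcg_state / 2147483647
  }

  startable <- function(s, t) {
    w <- wins[[s]]
    k <- which(w[, 1] <= t)
    if (!length(k)) return(FALSE)
    k <- k[length(k)]
    if (wtf[s]) {
      # work-to-finish: queued work continues past the close, but not past
      # midnight of the window's own day (a new day's session must wait for
      # its opening time) nor past the next window's opening
      t < min(max(w[k, 2L], 1440 * (w[k, 1L] %/% 1440 + 1)),
              if (k < nrow(w)) w[k + 1L, 1L] else Inf)
    } else t < w[k, 2L]
  }
  next_open <- function(s, t) {
    w <- wins[[s]]
    k <- which(w[, 1] > t)
    if (length(k)) w[k[1L], 1L] else Inf
  }
  ensure_wake <- function(s, t) {
    no <- next_open(s, t)
    if (is.finite(no) && (!is.finite(wake_at[s]) || wake_at[s] <= t ||
                          no < wake_at[s])) {
      wake_at[s] <<- no
      push(no, 0L, s, 3L)
    }
  }

  enqueue <- function(s, i) {
    if (qt[s] >= length(qbuf[[s]]))
      qbuf[[s]] <<- c(qbuf[[s]], integer(length(qbuf[[s]])))
    qt[s] <<- qt[s] + 1L
    qbuf[[s]][qt[s]] <<- i
  }

  take_server <- function(s) {
    fs <- free_srv[[s]]
    nf <- length(fs)
    j <- if (rnd[s] && nf > 1L) min(nf, 1L + as.integer(lcg() * nf))
         else which.min(fs)
    sv <- fs[j]
    free_srv[[s]] <<- fs[-j]
    sv
  }
  release <- function(s, sv) {
    busy[s] <<- busy[s] - 1L
    free_srv[[s]] <<- c(free_srv[[s]], sv)
  }

  start_primary <- function(i, s, t) {
    busy[s] <<- busy[s] + 1L
    if (busy[s] > cap[s]) stop("capacity exceeded at ", stations[[s]]$name)
    sv <- take_server(s)
    held_server[i] <<- sv
    row <- off[i] + cur[i]
    t_start[row] <<- t; srv_of[row] <<- sv
    stage[i] <<- 1L
    if (record_events) note(t, 2L, i, s)
    push(t + svc_flat[row], i, s, 2L)
  }
  start_ext <- function(i, s, t) {
    busy[s] <<- busy[s] + 1L
    if (busy[s] > cap[s]) stop("capacity exceeded at ", stations[[s]]$name)
    ext_server[i] <<- take_server(s)
    ext_start_t[i] <<- t
    stage[i] <<- 3L
    if (record_events) note(t, 2L, i, s)
    push(t + ext_dur[i], i, s, 4L)
  }

  try_start <- function(s, t) {
    while (busy[s] < cap[s] && qh[s] < qt[s]) {
      if (!startable(s, t)) { ensure_wake(s, t); break }
      qh[s] <<- qh[s] + 1L
      i <- qbuf[[s]][qh[s]]
      if (stage[i] == 2L) start_ext(i, s, t) else start_primary(i, s, t)
    }
  }

  advance <- function(i, t) {
    row <- off[i] + cur[i]
    t_end[row] <<- t
    stage[i] <<- 0L
    if (cur[i] == rlen[i]) {
      departure[i] <<- t
      if (record_events) note(t, 5L, i, 0L)
    } else {
      cur[i] <<- cur[i] + 1L
      nst <- route_flat[off[i] + cur[i]]
      if (record_events) note(t, 4L, i, nst)
      push(t + transfer[nst], i, nst, 1L)
    }
  }

  for (i in seq_len(n)) push(model$arrival[i], i, route_flat[off[i] + 1L], 1L)

  truncated <- FALSE
  while (hn > 0L) {
    evt <- pop()
    t <- evt[1L]; i <- evt[2L]; s <- evt[3L]; kind <- evt[4L]
    if (t > horizon) { truncated <- TRUE; break }
    if (kind == 1L) {                      # arrival at a station (queue join)
      row <- off[i] + cur[i]
      t_join[row] <- t
      if (record_events) note(t, 1L, i, s)
      if (busy[s] < cap[s] && qh[s] == qt[s] && startable(s, t)) {
        start_primary(i, s, t)
      } else {
        enqueue(s, i)
        if (!startable(s, t)) ensure_wake(s, t)
      }
    } else if (kind == 2L) {               # base service end
      if (stage[i] == 1L && !is.na(ext_step[i]) && cur[i] == ext_step[i]) {
        es <- ext_st[i]
        ext_join[i] <- t
        stage[i] <- 2L
        if (busy[es] < cap[es] && qh[es] == qt[es] && startable(es, t)) {
          start_ext(i, es, t)
        } else {
          enqueue(es, i)
          if (!startable(es, t)) ensure_wake(es, t)
        }
      } else {
        if (record_events) note(t, 3L, i, s)
        release(s, held_server[i]); held_server[i] <- NA_integer_
        advance(i, t)
        try_start(s, t)
      }
    } else if (kind == 4L) {               # extension end: release both
      es <- ext_st[i]
      ps <- route_flat[off[i] + cur[i]]
      ext_end_t[i] <- t
      if (record_events) note(t, 3L, i, es)
      release(es, ext_server[i]); ext_server[i] <- NA_integer_
      release(ps, held_server[i]); held_server[i] <- NA_integer_
      advance(i, t)
      try_start(ps, t)
      try_start(es, t)
    } else {                               # station wake at a window opening
      if (wake_at[s] <= t) wake_at[s] <- Inf
      if (record_events) note(t, 6L, 0L, s)
      try_start(s, t)
    }
  }

  if (!truncated && n && anyNA(departure)) {
    stuck <- which(is.na(departure))
    stop("run ended with ", length(stuck),
         " entities still in the system (first: entity ", stuck[1L],
         " at station ",
         stations[[route_flat[off[stuck[1L]] + cur[stuck[1L]]]]]$name,
         "); check station windows")
  }

  trail <- data.frame(
    entity = rep.int(seq_len(n), rlen),
    step = sequence(rlen),
    station = route_flat,
    t_join = t_join, t_start = t_start, t_end = t_end, server = srv_of)
  events <- if (record_events) {
    idx <- seq_len(ev_n)
    data.frame(time = ev_t[idx],
               kind = .event_kinds[ev_k[idx]],
               entity = ev_e[idx],
               station = ifelse(ev_s[idx] > 0L,
                                vapply(stations, `[[`, "", "name")[ev_s[idx]],
                                NA_character_))
  } else NULL

  structure(list(trail = trail, arrival = model$arrival,
                 departure = departure,
                 ext = data.frame(entity = seq_len(n), t_join = ext_join,
                                  t_start = ext_start_t, t_end = ext_end_t),
                 events = events, truncated = truncated,
                 station_names = vapply(stations, `[[`, "", "name")),
            class = "des_log")
}

#' @export
print.des_log <- function(x, ...) {
  cat(sprintf("<des_log> %d entities, %d stations%s\n",
              length(x$arrival), length(x$station_names),
              if (x$truncated) " (truncated at horizon)" else ""))
  cat(sprintf("  departures complete: %d/%d\n",
              sum(!is.na(x$departure)), length(x$departure)))
  invisible(x)
}

#' Per-entity wide timestamp table
#'
#' One row per entity, one `join/start/end` column triple per route step,
#' named by station (with `.2`, `.3` suffixes for repeat visits).
#'
#' @param log a `"des_log"`.
#' @return a data frame.
#' @export
entity_timestamps <- function(log) {
  tr <- log$trail
  n <- length(log$arrival)
  out <- data.frame(entity = seq_len(n), arrival = log$arrival,
                    departure = log$departure)
  if (!nrow(tr)) return(out)
  nm <- log$station_names[tr$station]
  # disambiguate repeat visits within an entity's route
  visit <- stats::ave(seq_along(nm), tr$entity, nm,
                      FUN = seq_along)
  nm <- ifelse(visit > 1L, paste0(nm, ".", visit), nm)
  for (col in c("t_join", "t_start", "t_end")) {
    wide <- tapply(tr[[col]], list(tr$entity, nm), identity)
    for (st in colnames(wide))
      out[[paste0(st, "_", sub("^t_", "", col))]] <- wide[, st]
  }
  out
}

#' Write an event log to CSV
#'
#' Writes the ordered event record (one row per event). Requires the log to
#' have been produced with `record_events = TRUE`.
#'
#' @param log a `"des_log"`.
#' @param file path to write.
#' @return the path, invisibly.
#' @export
write_eventlog <- function(log, file) {
  if (is.null(log$events)) stop("log has no event record")
  utils::write.csv(log$events, file, row.names = FALSE)
  invisible(file)
}
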