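# Independent brute-force next-event simulator used as the engine oracle.
# Same contract as des_run (FIFO queues, (time, insertion-order) event
# ordering, window/work-to-finish semantics, lowest-free-server assignment)
# but a deliberately naive implementation: a flat pending-event list scanned
# for its minimum, wake events pre-scheduled at every window opening, and a
# full station sweep after every event.

oracle_run <- function(stations, arrival, route, service, transfer = 0) {
  ns <- length(stations)
  n <- length(arrival)
  cap <- vapply(stations, `[[`, 1L, "capacity")
  wtf <- vapply(stations, `[[`, TRUE, "work_to_finish")
  wins <- lapply(stations, `[[`, "windows")
  if (length(transfer) == 1) transfer <- rep(transfer, ns)

  startable <- function(s, t) {
    w <- wins[[s]]
    ok <- FALSE
    for (k in seq_len(nrow(w))) {
      if (w[k, 1] > t) next
      if (wtf[s]) {
        bound <- max(w[k, 2], 1440 * (w[k, 1] %/% 1440 + 1))
        if (k < nrow(w)) bound <- min(bound, w[k + 1, 1])
        if (t < bound) ok <- TRUE
      } else if (t < w[k, 2]) ok <- TRUE
    }
    ok
  }

  rlen <- vapply(route, length, 1L)
  t_join <- lapply(rlen, function(k) rep(NA_real_, k))
  t_start <- lapply(rlen, function(k) rep(NA_real_, k))
  t_end <- lapply(rlen, function(k) rep(NA_real_, k))
  srv <- lapply(rlen, function(k) rep(NA_integer_, k))
  departure <- rep(NA_real_, n)

  cur <- rep(1L, n)
  queue <- rep(list(integer(0)), ns)
  free <- lapply(cap, seq_len)

  # pending events: list of c(time, seq, kind, ent, st); kind 1 arrive, 2 end
  pend <- list()
  seqc <- 0
  push <- function(time, kind, ent, st) {
    seqc <<- seqc + 1
    pend[[length(pend) + 1]] <<- c(time, seqc, kind, ent, st)
  }
  for (i in seq_len(n)) push(arrival[i], 1, i, route[[i]][1])
  for (s in seq_len(ns))
    for (k in seq_len(nrow(wins[[s]])))
      if (is.finite(wins[[s]][k, 1])) push(wins[[s]][k, 1], 3, 0, s)

  sweep <- function(t) {
    for (s in seq_len(ns)) {
      while (length(free[[s]]) > 0 && length(queue[[s]]) > 0 &&
             startable(s, t)) {
        i <- queue[[s]][1]
        queue[[s]] <<- queue[[s]][-1]
        sv <- min(free[[s]])
        free[[s]] <<- setdiff(free[[s]], sv)
        t_start[[i]][cur[i]] <<- t
        srv[[i]][cur[i]] <<- sv
        push(t + service[[i]][cur[i]], 2, i, s)
      }
    }
  }

  while (length(pend) > 0) {
    times <- vapply(pend, `[[`, 0, 1)
    seqs <- vapply(pend, `[[`, 0, 2)
    best <- which(times == min(times))
    best <- best[which.min(seqs[best])]
    e <- pend[[best]]
    pend[[best]] <- NULL
    t <- e[1]; kind <- e[3]; i <- e[4]; s <- e[5]
    if (kind == 1) {
      t_join[[i]][cur[i]] <- t
      queue[[s]] <- c(queue[[s]], i)
    } else if (kind == 2) {
      t_end[[i]][cur[i]] <- t
      free[[s]] <- c(free[[s]], srv[[i]][cur[i]])
      if (cur[i] == rlen[i]) departure[i] <- t
      else {
        cur[i] <- cur[i] + 1L
        push(t + transfer[route[[i]][cur[i]]], 1, i, route[[i]][cur[i]])
      }
    }
    sweep(t)
  }

  list(trail = data.frame(
         entity = rep.int(seq_len(n), rlen),
         step = sequence(rlen),
         station = unlist(route),
         t_join = unlist(t_join), t_start = unlist(t_start),
         t_end = unlist(t_end), server = unlist(srv)),
       departure = departure)
}

# random small system generator for the equivalence property
random_small_system <- function(seed) {
  set.seed(seed)
  ns <- sample(1:3, 1)
  n <- sample(1:10, 1)
  stations <- lapply(seq_len(ns), function(s) {
    wtf <- runif(1) < 0.5
    windows <- if (runif(1) < 0.5) matrix(c(0, Inf), 1)
    else matrix(c(round(runif(1, 0, 20), 2),
                  round(runif(1, 30, 80), 2)), 1)
    des_station(paste0("s", s), sample(1:2, 1), windows,
                work_to_finish = wtf)
  })
  route <- lapply(seq_len(n), function(i)
    sample(ns, sample(1:3, 1), replace = TRUE))
  service <- lapply(route, function(r) round(runif(length(r), 0.5, 10), 2))
  arrival <- round(runif(n, 0, 40), 2)
  transfer <- round(runif(1, 0, 2), 2)
  # ensure every non-work-to-finish window is long enough that no entity is
  # stranded (the engine raises an error for stranded entities)
  list(stations = lapply(stations, function(st) {
    if (!st$work_to_finish && is.finite(st$windows[1, 2]))
      st$windows[1, 2] <- 2000
    st
  }), route = route, service = service, arrival = arrival,
  transfer = transfer)
}
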