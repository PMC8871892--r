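# The event-calendar engine: hand traces, FIFO/capacity invariants, Lindley
# recursion, and exact equivalence with the brute-force oracle.

test_that("single-server FIFO hand trace is reproduced exactly", {
  m <- des_model(list(des_station("s", 1)), arrival = c(0, 1, 2),
                 route = list(1L, 1L, 1L), service = list(5, 5, 5))
  log <- des_run(m)
  expect_equal(log$trail$t_start - log$trail$t_join, c(0, 4, 8))
  expect_equal(log$departure, c(5, 10, 15))
})

test_that("two-server deterministic trace: four simultaneous arrivals", {
  m <- des_model(list(des_station("s", 2)), arrival = c(0, 0, 0, 0),
                 route = rep(list(1L), 4), service = rep(list(10), 4))
  expect_equal(des_run(m)$departure, c(10, 10, 20, 20))
})

test_that("an empty model terminates with an empty log", {
  m <- des_model(list(des_station("s", 1)), arrival = numeric(0),
                 route = list(), service = list())
  log <- des_run(m)
  expect_identical(nrow(log$trail), 0L)
  expect_identical(nrow(log$events), 0L)
})

test_that("a free resource is seized immediately; a busy one queues FIFO", {
  m <- des_model(list(des_station("s", 1)), arrival = c(0, 1),
                 route = list(1L, 1L), service = list(10, 1))
  log <- des_run(m)
  expect_equal(log$trail$t_start[1], 0)        # free: zero wait
  expect_equal(log$trail$t_start[2], 10)       # starts exactly at service_end
})

test_that("invalid models are rejected", {
  st <- list(des_station("s", 1))
  expect_error(des_model(st, 0, list(2L), list(1)), "unknown station")
  expect_error(des_model(st, 0, list(1L), list(-1)), "non-negative")
  expect_error(des_model(st, c(0, 1), list(1L), list(1)), "per entity")
  expect_error(des_station("s", 0), "positive integer")
})

test_that("service starts honour opening windows; work-to-finish continues past close", {
  # opens 9:00, closes 10:00; arrivals before open wait for it
  wtf <- des_model(list(des_station("c", 1, matrix(c(540, 600), 1),
                                    work_to_finish = TRUE)),
                   arrival = c(500, 505, 510),
                   route = rep(list(1L), 3), service = rep(list(30), 3))
  log <- des_run(wtf)
  expect_equal(log$trail$t_start, c(540, 570, 600))  # third starts past close
  expect_equal(log$departure, c(570, 600, 630))

  # same but not work-to-finish with a later second window: third waits for it
  two <- des_model(list(des_station("c", 1,
                                    matrix(c(540, 600, 700, 800), 2,
                                           byrow = TRUE),
                                    work_to_finish = FALSE)),
                   arrival = c(500, 505, 510),
                   route = rep(list(1L), 3), service = rep(list(30), 3))
  log2 <- des_run(two)
  expect_equal(log2$trail$t_start, c(540, 570, 700))
})

test_that("work-to-finish never starts a new day's work before that day's opening", {
  # two daily windows 9:00-13:00; an entity arriving early on day 2 must
  # wait for day 2's opening, not ride day 1's extension
  m <- des_model(list(des_station("c", 1, daily_windows("09:00", "13:00", 2))),
                 arrival = 1440 + 500, route = list(1L), service = list(5))
  expect_equal(des_run(m)$trail$t_start, 1440 + 540)
})

test_that("the extension co-seizes the secondary resource and releases both", {
  # entity 1 consults 10 min then needs the specialist for 5; entity 2's
  # discussion must wait for the single specialist
  st <- list(des_station("room", 2), des_station("spec", 1))
  m <- des_model(st, arrival = c(0, 0), route = list(1L, 1L),
                 service = list(10, 10),
                 ext_step = c(1L, 1L), ext_station = c(2L, 2L),
                 ext_dur = c(5, 5))
  log <- des_run(m)
  expect_equal(log$ext$t_start, c(10, 15))
  expect_equal(log$ext$t_end, c(15, 20))
  # rooms held throughout the discussion
  expect_equal(log$trail$t_end, c(15, 20))
})

test_that("Lindley recursion holds for a single always-open FIFO server", {
  set.seed(31)
  for (rep in 1:20) {
    n <- 30
    arrival <- sort(runif(n, 0, 100))
    service <- runif(n, 0.5, 8)
    m <- des_model(list(des_station("s", 1)), arrival,
                   route = rep(list(1L), n), service = as.list(service))
    log <- des_run(m)
    wait <- numeric(n); dep <- numeric(n)
    for (i in seq_len(n)) {
      wait[i] <- if (i == 1) 0 else max(0, dep[i - 1] - arrival[i])
      dep[i] <- arrival[i] + wait[i] + service[i]
    }
    expect_equal(log$trail$t_start - log$trail$t_join, wait)
    expect_equal(log$departure, dep)
  }
})

test_that("start order within each station equals queue-join order (FIFO property)", {
  set.seed(17)
  for (rep in 1:100) {
    sys <- random_small_system(sample.int(1e6, 1))
    m <- des_model(sys$stations, sys$arrival, sys$route, sys$service,
                   transfer = sys$transfer)
    log <- des_run(m)
    for (s in seq_along(sys$stations)) {
      rows <- log$trail[log$trail$station == s, ]
      ord <- order(rows$t_join, rows$t_start)
      expect_false(is.unsorted(rows$t_start[ord]))
    }
  }
})

test_that("engine trace matches the brute-force oracle exactly on 500 random systems", {
  for (seed in 1:500) {
    sys <- random_small_system(seed)
    m <- des_model(sys$stations, sys$arrival, sys$route, sys$service,
                   transfer = sys$transfer)
    log <- des_run(m, record_events = FALSE)
    orc <- oracle_run(sys$stations, sys$arrival, sys$route, sys$service,
                      sys$transfer)
    expect_equal(log$trail, orc$trail, tolerance = 1e-9,
                 label = paste("system seed", seed))
    expect_equal(log$departure, orc$departure, tolerance = 1e-9)
  }
})

test_that("capacity and entity conservation hold on random systems", {
  set.seed(4242)
  for (rep in 1:25) {
    sys <- random_small_system(sample.int(1e6, 1))
    m <- des_model(sys$stations, sys$arrival, sys$route, sys$service,
                   transfer = sys$transfer)
    log <- des_run(m)
    # conservation: every admitted entity departs; join <= start <= end
    expect_false(anyNA(log$departure))
    expect_true(all(log$trail$t_join <= log$trail$t_start + 1e-12))
    expect_true(all(log$trail$t_start <= log$trail$t_end + 1e-12))
    # capacity: count overlapping services per station at every start epoch
    for (s in seq_along(sys$stations)) {
      rows <- log$trail[log$trail$station == s, ]
      cap <- sys$stations[[s]]$capacity
      for (t in rows$t_start)
        expect_lte(sum(rows$t_start <= t & rows$t_end > t), cap)
    }
  }
})

test_that("random server assignment is uniform across free servers", {
  # arrivals spaced so all 7 servers are always free at each arrival
  n <- 7000
  m <- des_model(list(des_station("c", 7, random_assign = TRUE)),
                 arrival = seq(0, by = 5, length.out = n),
                 route = rep(list(1L), n), service = rep(list(1), n))
  log <- des_run(m, assign_seed = 77)
  share <- tabulate(log$trail$server, 7) / n
  se <- sqrt((1 / 7) * (6 / 7) / n)
  expect_true(all(abs(share - 1 / 7) < 3.5 * se))
})

test_that("the horizon truncates processing and flags the log", {
  m <- des_model(list(des_station("s", 1)), arrival = c(0, 100),
                 route = list(1L, 1L), service = list(5, 5))
  log <- des_run(m, horizon = 50)
  expect_true(log$truncated)
  expect_true(is.na(log$departure[2]))
})

test_that("entity_timestamps produces one wide row per entity", {
  st <- list(des_station("a", 1), des_station("b", 1))
  m <- des_model(st, arrival = c(0, 1), route = list(c(1L, 2L), c(1L, 2L)),
                 service = list(c(2, 3), c(2, 3)))
  wide <- entity_timestamps(des_run(m))
  expect_identical(nrow(wide), 2L)
  expect_true(all(c("a_join", "a_start", "a_end", "b_end") %in% names(wide)))
  expect_equal(wide$departure, wide$b_end)
})
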