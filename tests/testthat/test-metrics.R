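# Turnaround times, hourly crowd, percent change, rank tests.

test_that("turnaround times are the published subtractions", {
  # arrival 07:00, O&G registration done 07:45, departure 09:24
  spec <- data.frame(class = "OBS", arrival = hm("07:00"),
                     reg_end = hm("07:45"), departure = hm("09:24"))
  tt <- turnaround_times(fake_clinic_run(spec))
  expect_equal(tt$registration_tt, 45)
  expect_equal(tt$clinic_tt, 99)
  expect_equal(tt$overall_tt, 144)
  expect_equal(tt$overall_tt, tt$registration_tt + tt$clinic_tt)
})

test_that("private registration is measured at the private counter", {
  spec <- data.frame(class = "PRIVATE", arrival = hm("11:30"),
                     reg_end = hm("11:44"), departure = hm("12:50"))
  tt <- turnaround_times(fake_clinic_run(spec))
  expect_equal(tt$registration_tt, 14)
  expect_equal(tt$clinic_tt, 66)
})

test_that("pooled medians match an independent recomputation on 20 random logs", {
  set.seed(88)
  for (case in 1:20) {
    n <- sample(5:40, 1)
    arrival <- sort(runif(n, hm("07:00"), hm("11:00")))
    reg_end <- arrival + runif(n, 5, 60)
    departure <- reg_end + runif(n, 20, 150)
    cls <- sample(c("OBS", "GYN", "PRIVATE"), n, replace = TRUE)
    tt <- turnaround_times(fake_clinic_run(
      data.frame(class = cls, arrival = arrival, reg_end = reg_end,
                 departure = departure)))
    # spreadsheet-style recomputation from the raw timestamps
    expect_equal(median(tt$registration_tt), median(reg_end - arrival))
    expect_equal(median(tt$clinic_tt), median(departure - reg_end))
    for (g in unique(cls))
      expect_equal(median(tt$overall_tt[tt$class == g]),
                   median((departure - arrival)[cls == g]))
  }
})

test_that("a patient without departure violates conservation and errors", {
  spec <- data.frame(class = "OBS", arrival = 420, reg_end = 460,
                     departure = NA_real_)
  expect_error(turnaround_times(fake_clinic_run(spec)), "without a departure")
})

test_that("hourly crowd: empty log gives zeros; half-hour presence gives 0.5", {
  empty <- fake_clinic_run(data.frame(class = character(),
                                      arrival = numeric(),
                                      reg_end = numeric(),
                                      departure = numeric()))
  expect_true(all(hourly_crowd(empty) == 0))

  one <- fake_clinic_run(data.frame(class = "OBS", arrival = hm("09:00"),
                                    reg_end = hm("09:10"),
                                    departure = hm("09:40")))
  cr <- hourly_crowd(one)
  expect_equal(unname(cr["09:00"]), 0.5)
  expect_true(all(cr[names(cr) != "09:00"] == 0))
})

test_that("in-service intervals are excluded from the crowd", {
  spec <- data.frame(class = "OBS", arrival = hm("09:00"),
                     reg_end = hm("09:00"), departure = hm("10:00"))
  spec$service <- list(list(c(hm("09:20"), hm("09:50"))))
  cr <- hourly_crowd(fake_clinic_run(spec))
  expect_equal(unname(cr["09:00"]), 0.5)  # 60 - 30 in service = 30 waiting
})

test_that("hourly crowd equals a brute-force per-minute recount on random logs", {
  set.seed(303)
  for (case in 1:8) {
    n <- sample(3:12, 1)
    arrival <- runif(n, hm("07:30"), hm("13:00"))
    reg_end <- arrival + runif(n, 2, 40)
    departure <- reg_end + runif(n, 30, 180)
    service <- lapply(seq_len(n), function(i) {
      k <- sample(0:2, 1)
      if (k == 0) return(list())
      # sequential, non-overlapping in-service intervals (a patient is at
      # one station at a time)
      out <- list(); cursor <- reg_end[i]
      for (j in seq_len(k)) {
        s0 <- cursor + runif(1, 0, 15)
        e0 <- min(departure[i], s0 + runif(1, 1, 20))
        if (s0 >= departure[i]) break
        out[[length(out) + 1]] <- c(s0, e0)
        cursor <- e0
      }
      out
    })
    spec <- data.frame(class = sample(c("OBS", "PRIVATE"), n, TRUE),
                       arrival = arrival, reg_end = reg_end,
                       departure = departure)
    spec$service <- service
    expect_equal(hourly_crowd(fake_clinic_run(spec)), crowd_recount(spec),
                 tolerance = 1e-12)
  }
})

test_that("percent change is plain arithmetic with a positive-base guard", {
  expect_equal(percent_change(60, 100), -40)
  expect_equal(percent_change(100, 100), 0)
  expect_equal(percent_change(138, 120), 15)
  expect_error(percent_change(10, 0), "positive")
})

test_that("Mann-Whitney on {1,2,3} vs {4,5,6}: U = 0, exact one-sided p = 1/20", {
  rt <- rank_tests(list(c(1, 2, 3), c(4, 5, 6)))
  expect_identical(rt$method, "Mann-Whitney")
  expect_equal(rt$statistic, 0)
  expect_equal(rt$p.exact.less, 1 / 20)
  # asymptotic matches wilcox.test's tie-corrected normal approximation
  expect_equal(rt$p.value,
               suppressWarnings(wilcox.test(c(1, 2, 3), c(4, 5, 6),
                                            exact = FALSE,
                                            correct = FALSE))$p.value)
})

test_that("exact Mann-Whitney agrees with full enumeration on random tiny samples", {
  set.seed(9)
  for (case in 1:10) {
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
    x <- round(runif(n1 + n2, 0, 10), 1)
    rt <- rank_tests(list(x[1:n1], x[(n1 + 1):(n1 + n2)]))
    # independent enumeration of all C(n, n1) splits
    r <- rank(x)
    u_obs <- sum(r[1:n1]) - n1 * (n1 + 1) / 2
    us <- apply(combn(n1 + n2, n1), 2,
                function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
    expect_equal(rt$p.exact.less, mean(us <= u_obs))
    expect_equal(rt$p.exact.greater, mean(us >= u_obs))
  }
})

test_that("identical groups give a near-zero Kruskal-Wallis H and p near 1", {
  rt <- rank_tests(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_identical(rt$method, "Kruskal-Wallis")
  expect_lt(rt$statistic, 1e-9)
  expect_gt(rt$p.value, 0.99)
  expect_equal(rt$p.exact, 1)
})

test_that("degenerate group lists are rejected", {
  expect_error(rank_tests(list(1:3)), "two groups")
  expect_error(rank_tests(list(1:3, numeric(0))), "non-empty")
})

test_that("scaling all waits up increases every overall TT and no crowd value drops", {
  set.seed(55)
  n <- 12
  arrival <- runif(n, hm("08:00"), hm("10:00"))
  svc <- runif(n, 5, 15)
  wait <- runif(n, 10, 60)
  mk <- function(lambda) {
    reg_end <- arrival + 5
    departure <- reg_end + lambda * wait + svc
    spec <- data.frame(class = "OBS", arrival = arrival, reg_end = reg_end,
                       departure = departure)
    spec$service <- lapply(seq_len(n), function(i)
      list(c(reg_end[i] + lambda * wait[i], departure[i])))
    spec
  }
  base <- mk(1); stretched <- mk(1.5)
  tt1 <- turnaround_times(fake_clinic_run(base))
  tt2 <- turnaround_times(fake_clinic_run(stretched))
  expect_true(all(tt2$overall_tt > tt1$overall_tt))
  expect_true(all(hourly_crowd(fake_clinic_run(stretched)) >=
                    hourly_crowd(fake_clinic_run(base)) - 1e-12))
})
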