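# Outcome measures: turnaround times, hourly waiting-area crowding,
# percentage change versus base case, and rank-based group comparisons.

#' Turnaround times per patient
#'
#' Computes the three published turnaround-time (TT) measures for every O&G
#' patient of a completed run:
#'
#' * registration TT — public: completion of O&G-counter registration minus
#'   arrival at the QMS counter; private: completion of private-counter
#'   registration minus arrival;
#' * clinic TT — departure minus completion of the registration above;
#' * overall TT — departure minus first arrival.
#'
#' General (non-O&G) patients and downtime blockers are not O&G clinic
#' patients and are excluded.
#'
#' @param run a `"clinic_run"` from [simulate_replication()].
#' @return a data frame with `patient`, `class` (`OBS`/`GYN`/`PRIVATE`),
#'   `day`, `registration_tt`, `clinic_tt`, `overall_tt` (minutes).
#' @export
turnaround_times <- function(run) {
  stopifnot(inherits(run, "clinic_run"))
  tr <- run$log$trail
  p <- run$patients
  if (anyNA(run$log$departure[p$class %in% c("OBS", "GYN", "PRIVATE")]))
    stop("run has O&G patients without a departure")
  pub_rows <- which(tr$station == .stn("OG_COUNTER"))
  priv_rows <- which(tr$station == .stn("PRIVATE_COUNTER") & tr$step == 1L)
  rows <- c(pub_rows, priv_rows)
  ent <- tr$entity[rows]
  reg_done <- tr$t_end[rows]
  out <- data.frame(patient = ent, class = p$class[ent], day = p$day[ent],
                    registration_tt = reg_done - p$abs_time[ent],
                    clinic_tt = run$log$departure[ent] - reg_done,
                    overall_tt = run$log$departure[ent] - p$abs_time[ent])
  out <- out[order(out$patient), ]
  rownames(out) <- NULL
  out
}

#' Hourly waiting-area crowd
#'
#' For every clock minute, counts the patients who have completed O&G (or
#' private) counter registration, have not yet departed, and are not
#' currently receiving service at any station — i.e. the patients sitting in
#' the clinic waiting area. The hourly value is the mean of the 60
#' per-minute counts, averaged over the run's days; hours are left-closed
#' clock hours 07:00-16:00.
#'
#' @param run a `"clinic_run"`.
#' @param hours integer vector of clock hours to report (default 7:16).
#' @param snapshot if `TRUE`, report the on-the-hour count instead of the
#'   hourly mean.
#' @return a named numeric vector, one value per hour (mean patients present,
#'   per day).
#' @export
hourly_crowd <- function(run, hours = 7:16, snapshot = FALSE) {
  stopifnot(inherits(run, "clinic_run"))
  tr <- run$log$trail
  p <- run$patients
  days <- run$days
  total_min <- 1440L * days
  delta <- numeric(total_min + 1L)

  pub_rows <- which(tr$station == .stn("OG_COUNTER"))
  priv_rows <- which(tr$station == .stn("PRIVATE_COUNTER") & tr$step == 1L)
  rows <- c(pub_rows, priv_rows)
  ent <- tr$entity[rows]
  reg_done <- tr$t_end[rows]
  dep <- run$log$departure[ent]

  add <- function(from, to, wt) {
    # present at integer minute m iff from <= m < to
    a <- ceiling(from) + 1L   # +1: minute 0 is index 1
    b <- ceiling(to)
    ok <- which(b >= a)
    if (length(ok)) {
      a <- pmax(a[ok], 1L); b <- pmin(b[ok], total_min)
      keep <- a <= b
      if (any(keep)) {
        av <- a[keep]; bv <- b[keep]
        for (j in seq_along(av)) {
          delta[av[j]] <<- delta[av[j]] + wt
          delta[bv[j] + 1L] <<- delta[bv[j] + 1L] - wt
        }
      }
    }
  }
  add(reg_done, dep, 1)

  # subtract in-service intervals of registered O&G patients (stations after
  # registration, including the payment visit), and discussion extensions
  og_ent <- ent
  after_reg <- tr$entity %in% og_ent & !is.na(tr$t_start) &
    !(tr$station %in% c(.stn("QMS"), .stn("REVENUE"))) &
    !(tr$station == .stn("OG_COUNTER")) &
    !(tr$station == .stn("PRIVATE_COUNTER") & tr$step == 1L)
  add(tr$t_start[after_reg], tr$t_end[after_reg], -1)

  counts <- cumsum(delta[seq_len(total_min)])
  per_min <- matrix(counts, nrow = 1440L)  # minute-of-day x day
  if (snapshot) {
    vals <- per_min[hours * 60L + 1L, , drop = FALSE]
    out <- rowMeans(vals)
  } else {
    out <- vapply(hours, function(h)
      mean(per_min[h * 60L + seq_len(60L), , drop = FALSE]), 0)
  }
  names(out) <- sprintf("%02d:00", hours)
  out
}

#' Percentage change of a scenario statistic versus the base case
#'
#' `100 * (scenario - base) / base`; negative values are reductions.
#'
#' @param scenario_stat,base_stat numeric (scalars or equal-length vectors);
#'   `base_stat` must be strictly positive.
#' @return percentage change(s).
#' @examples
#' percent_change(60, 100)   # -40
#' percent_change(138, 120)  # +15
#' @export
percent_change <- function(scenario_stat, base_stat) {
  if (any(base_stat <= 0)) stop("base_stat must be strictly positive")
  100 * (scenario_stat - base_stat) / base_stat
}

#' Rank-based comparison of two or more groups
#'
#' Mann-Whitney (two groups) or Kruskal-Wallis (three or more), with the
#' tie-corrected asymptotic p-value. For small samples (combined n <= 12 by
#' default) an exact permutation p-value is computed alongside by full
#' enumeration of group assignments.
#'
#' @param samples a list of numeric vectors, one per group (>= 2 non-empty
#'   groups).
#' @param exact_max_n largest combined sample size for which the exact
#'   permutation p-value is also computed.
#' @return an object of class `"rank_test"`: `method`, `statistic`,
#'   `p.value` (asymptotic), and for small samples `p.exact` (two-sided for
#'   Mann-Whitney via the doubled smaller tail; upper tail for
#'   Kruskal-Wallis) plus `p.exact.less`/`p.exact.greater` one-sided tails
#'   (Mann-Whitney only).
#' @examples
#' rank_tests(list(c(1, 2, 3), c(4, 5, 6)))
#' @export
rank_tests <- function(samples, exact_max_n = 12) {
  if (!is.list(samples) || length(samples) < 2)
    stop("need a list of at least two groups")
  if (any(vapply(samples, length, 1L) == 0))
    stop("every group must be non-empty")
  k <- length(samples)
  n <- vapply(samples, length, 1L)
  x <- unlist(samples, use.names = FALSE)
  g <- factor(rep.int(seq_len(k), n))

  if (k == 2) {
    ht <- suppressWarnings(
      stats::wilcox.test(samples[[1]], samples[[2]], exact = FALSE,
                         correct = FALSE))
    method <- "Mann-Whitney"
    statistic <- unname(ht$statistic)  # U for group 1
  } else {
    ht <- stats::kruskal.test(x, g)
    method <- "Kruskal-Wallis"
    statistic <- unname(ht$statistic)
  }
  out <- list(method = method, statistic = statistic,
              p.value = unname(ht$p.value), n = n)

  if (sum(n) <= exact_max_n) {
    if (k == 2) {
      u_of <- function(idx1) {
        r <- rank(x)
        sum(r[idx1]) - n[1] * (n[1] + 1) / 2
      }
      all1 <- utils::combn(sum(n), n[1])
      us <- apply(all1, 2, u_of)
      u_obs <- u_of(seq_len(n[1]))
      p_less <- mean(us <= u_obs)
      p_greater <- mean(us >= u_obs)
      out$p.exact.less <- p_less
      out$p.exact.greater <- p_greater
      out$p.exact <- min(1, 2 * min(p_less, p_greater))
    } else {
      h_of <- function(assign) {
        stats::kruskal.test(x, factor(assign))$statistic
      }
      perms <- .group_assignments(n)
      hs <- apply(perms, 2, h_of)
      out$p.exact <- mean(hs >= statistic - 1e-12)
    }
  }
  structure(out, class = "rank_test")
}

# all distinct assignments of sum(n) items to groups of sizes n (columns),
# built by choosing each group's members among the items still unassigned
.group_assignments <- function(n) {
  total <- sum(n)
  assigns <- list(integer(total))
  remaining <- list(seq_len(total))
  for (gi in seq_along(n)[-length(n)]) {
    new_assigns <- list(); new_remaining <- list()
    for (j in seq_along(assigns)) {
      av <- remaining[[j]]
      ch <- utils::combn(length(av), n[gi])
      for (cc in seq_len(ncol(ch))) {
        a <- assigns[[j]]
        take <- av[ch[, cc]]
        a[take] <- gi
        new_assigns[[length(new_assigns) + 1L]] <- a
        new_remaining[[length(new_remaining) + 1L]] <- setdiff(av, take)
      }
    }
    assigns <- new_assigns; remaining <- new_remaining
  }
  k <- length(n)
  out <- matrix(0L, total, length(assigns))
  for (j in seq_along(assigns)) {
    a <- assigns[[j]]
    a[remaining[[j]]] <- k
    out[, j] <- a
  }
  out
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("<rank_test> %s: statistic = %.4g, asymptotic p = %.4g\n",
              x$method, x$statistic, x$p.value))
  if (!is.null(x$p.exact))
    cat(sprintf("  exact permutation p = %.4g\n", x$p.exact))
  invisible(x)
}
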