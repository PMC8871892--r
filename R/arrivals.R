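#' Arrival schedule for one patient stream
#'
#' Describes how one class of patients arrives over a clinic day. Arrivals
#' fall into 30-minute slots starting at `registration_open` and ending with
#' the slot that starts at `last_slot_start`. Two patterns are supported:
#'
#' * `"block_random"` — the uncontrolled pattern: each patient's slot is a
#'   weighted random draw (weights shaped to peak in the first open hours),
#'   subject to the per-slot cap;
#' * `"even_staggered"` — appointment-style staggering: the daily total is
#'   split as evenly as possible across slots (earlier slots take the
#'   remainder), never exceeding the cap.
#'
#' Within a slot arrival times are uniform.
#'
#' @param pattern `"block_random"` or `"even_staggered"`.
#' @param registration_open clock time (`"HH:MM"` or minutes) of the first
#'   slot.
#' @param last_slot_start clock time of the final slot's start.
#' @param per_slot_cap maximum arrivals per 30-minute slot (may be `Inf`).
#' @param daily_total number of arrivals per day.
#' @param patient_class one of `"PUBLIC"`, `"PRIVATE"`, `"GENERAL"` (public
#'   O&G patients arrive on a single shared schedule; the obstetrics/
#'   gynaecology split is an attribute, see [assign_attributes()]).
#' @param weights optional per-slot weight vector for `"block_random"`
#'   (recycled/validated against the slot count); defaults to the package's
#'   morning-peak shape via [peak_weights()].
#' @param slot_width slot width in minutes; fixed at 30.
#' @return an object of class `"arrival_schedule"`.
#' @examples
#' arrival_schedule("even_staggered", "07:30", "11:30", 10, 86, "PUBLIC")
#' @export
arrival_schedule <- function(pattern = c("block_random", "even_staggered"),
                             registration_open, last_slot_start,
                             per_slot_cap, daily_total,
                             patient_class = c("PUBLIC", "PRIVATE", "GENERAL"),
                             weights = NULL, slot_width = 30) {
  pattern <- match.arg(pattern)
  patient_class <- match.arg(patient_class)
  if (slot_width != 30) stop("slot_width is fixed at 30 minutes")
  open <- hm(registration_open); last <- hm(last_slot_start)
  if (last < open) stop("last_slot_start must not precede registration_open")
  if (daily_total < 0 || daily_total != round(daily_total))
    stop("daily_total must be a non-negative integer")
  if (!is.infinite(per_slot_cap) &&
      (per_slot_cap < 0 || per_slot_cap != round(per_slot_cap)))
    stop("per_slot_cap must be a non-negative integer or Inf")
  n_slots <- (last - open) %/% slot_width + 1L
  if (daily_total > per_slot_cap * n_slots)
    stop(sprintf(
      "infeasible schedule: daily_total %d exceeds cap %s x %d slots",
      daily_total, format(per_slot_cap), n_slots))
  if (!is.null(weights)) {
    if (length(weights) != n_slots)
      stop("weights must have one entry per slot (", n_slots, ")")
    if (any(weights < 0) || sum(weights) <= 0) stop("invalid weights")
    weights <- weights / sum(weights)
  } else if (pattern == "block_random") {
    weights <- peak_weights(n_slots, open)
  }
  structure(list(pattern = pattern, registration_open = open,
                 last_slot_start = last, per_slot_cap = per_slot_cap,
                 daily_total = as.integer(daily_total),
                 patient_class = patient_class, weights = weights,
                 slot_width = 30, n_slots = n_slots),
            class = "arrival_schedule")
}

#' @export
print.arrival_schedule <- function(x, ...) {
  cat(sprintf(
    "<arrival_schedule> %s %s: %d/day over %d slots (%s-%s), cap %s/slot\n",
    x$patient_class, x$pattern, x$daily_total, x$n_slots,
    fmt_clock(x$registration_open), fmt_clock(x$last_slot_start),
    format(x$per_slot_cap)))
  invisible(x)
}

#' Morning-peak slot weights for block arrivals
#'
#' Default weight shape for the uncontrolled ("block") arrival pattern:
#' roughly 60% of the day's arrivals fall between 08:00 and 10:00, with a
#' gentle ramp before and a geometric tail after. Slots that start before
#' 08:00 ramp up; the four slots from 08:00 carry weight 0.15 each; later
#' slots decay by 25% per slot.
#'
#' @param n_slots number of 30-minute slots.
#' @param open clock minutes of the first slot.
#' @return a normalised weight vector of length `n_slots`.
#' @export
peak_weights <- function(n_slots, open = hm("07:00")) {
  starts <- open + 30 * (seq_len(n_slots) - 1L)
  w <- numeric(n_slots)
  pre <- starts < hm("08:00")
  peak <- starts >= hm("08:00") & starts < hm("10:00")
  post <- starts >= hm("10:00")
  w[pre] <- 0.04 + 0.02 * seq_len(sum(pre))
  w[peak] <- 0.15
  w[post] <- 0.12 * 0.75^(seq_len(sum(post)) - 1L)
  if (!any(peak)) w[] <- 1  # degenerate window: uniform
  w / sum(w)
}

#' Generate seeded arrivals for several clinic days
#'
#' Realises an [arrival_schedule()] over `n_days` days. For
#' `"even_staggered"`, per-slot counts are the daily total split as evenly as
#' possible (earlier slots take the remainder). For `"block_random"`, each
#' patient's slot is drawn from the schedule's weight vector, re-normalised
#' over slots that still have spare capacity, so no slot ever exceeds its
#' cap. In both cases arrival instants are uniform within the slot and the
#' output is sorted by day then time. The same seed always reproduces the
#' same list byte for byte.
#'
#' @param schedule an [arrival_schedule()].
#' @param n_days number of consecutive clinic days.
#' @param seed integer seed for this stream.
#' @return a data frame with columns `day` (1-based), `time` (clock minutes
#'   within the day), `abs_time` (minutes from midnight of day 1), `slot`
#'   (1-based slot index), `class`, and `k` (per-day arrival counter in time
#'   order, used to align draws across scenarios).
#' @examples
#' s <- arrival_schedule("even_staggered", "07:30", "11:30", 10, 86, "PUBLIC")
#' a <- generate_arrivals(s, n_days = 1, seed = 1)
#' table(a$slot)
#' @export
generate_arrivals <- function(schedule, n_days = 1, seed = 1) {
  stopifnot(inherits(schedule, "arrival_schedule"))
  with_seed(seed, {
    out <- vector("list", n_days)
    for (d in seq_len(n_days)) {
      counts <- slot_counts(schedule)
      if (sum(counts) == 0) next
      slot <- rep.int(seq_along(counts), counts)
      tim <- schedule$registration_open + 30 * (slot - 1L) + stats::runif(length(slot), 0, 30)
      ord <- order(tim)
      out[[d]] <- data.frame(day = d, time = tim[ord], slot = slot[ord],
                             k = seq_along(slot))
    }
    out <- out[!vapply(out, is.null, TRUE)]
    if (!length(out))
      return(data.frame(day = integer(), time = numeric(),
                        abs_time = numeric(), slot = integer(),
                        class = character(), k = integer()))
    res <- do.call(rbind, out)
    res$abs_time <- day_offset(res$day) + res$time
    res$class <- schedule$patient_class
    rownames(res) <- NULL
    res[, c("day", "time", "abs_time", "slot", "class", "k")]
  })
}

# Per-slot counts for one day (consumes RNG only for block_random).
slot_counts <- function(schedule) {
  n <- schedule$daily_total
  ns <- schedule$n_slots
  cap <- schedule$per_slot_cap
  if (n == 0) return(integer(ns))
  if (schedule$pattern == "even_staggered") {
    base <- n %/% ns
    rem <- n %% ns
    counts <- rep.int(base, ns) + c(rep.int(1L, rem), rep.int(0L, ns - rem))
  } else {
    w <- schedule$weights
    counts <- integer(ns)
    if (is.infinite(cap)) {
      draw <- sample.int(ns, n, replace = TRUE, prob = w)
      counts <- tabulate(draw, ns)
    } else {
      # sequential draw with renormalisation over non-full slots
      for (i in seq_len(n)) {
        openw <- w * (counts < cap)
        s <- sample.int(ns, 1L, prob = openw)
        counts[s] <- counts[s] + 1L
      }
    }
  }
  stopifnot(sum(counts) == n, all(counts <= cap))
  counts
}

#' Write an arrival list to CSV
#'
#' Exports the output of [generate_arrivals()] (optionally merged with
#' attributes) with a human-readable `clock_time` column.
#'
#' @param arrivals data frame from [generate_arrivals()].
#' @param file path to write.
#' @return the file path, invisibly.
#' @export
write_arrivals <- function(arrivals, file) {
  out <- arrivals
  out$clock_time <- fmt_clock(out$time)
  utils::write.csv(out, file, row.names = FALSE)
  invisible(file)
}
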