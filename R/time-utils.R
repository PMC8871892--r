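#' Parse a clock time to minutes after midnight
#'
#' Clock fields throughout the package are 24-hour `"HH:MM"` strings; all
#' durations are minutes. `hm()` converts a clock string (or a numeric already
#' in minutes, returned unchanged) to minutes after midnight.
#'
#' @param x character vector of `"HH:MM"` strings, or numeric minutes.
#' @return numeric vector of minutes after midnight.
#' @examples
#' hm("07:30")  # 450
#' hm(c("09:00", "13:30"))
#' @export
hm <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("invalid clock time: ", paste(x[bad], collapse = ", "))
  vapply(m, function(p) as.numeric(p[2]) * 60 + as.numeric(p[3]), 0)
}

#' Format minutes after midnight as "HH:MM"
#'
#' @param x numeric vector of minutes after midnight (day offsets are folded
#'   out with modulo 1440).
#' @return character vector of `"HH:MM"` strings (minutes are floored).
#' @examples
#' fmt_clock(450)       # "07:30"
#' fmt_clock(1440 + 90) # "01:30" on the following day
#' @export
fmt_clock <- function(x) {
  x <- floor(x) %% 1440
  sprintf("%02d:%02d", x %/% 60, x %% 60)
}

# Simulation time is continuous minutes from midnight of day 1; clinic days
# are laid end-to-end, so clock t on (1-based) day d maps to 1440*(d-1) + t.
day_offset <- function(day) 1440 * (day - 1)
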