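# Base-graphics plot methods.

#' Plot a fitted service-time distribution
#'
#' Density curve with the target quartiles marked.
#'
#' @param x a `"service_dist"`.
#' @param ... passed to [graphics::curve()].
#' @return `x`, invisibly.
#' @export
plot.service_dist <- function(x, ...) {
  if (x$family == "point_mass") {
    graphics::plot(c(x$value, x$value), c(0, 1), type = "h", lwd = 3,
                   xlab = "minutes", ylab = "", main = "point mass")
    return(invisible(x))
  }
  upper <- stats::qlnorm(0.995, x$meanlog, x$sdlog)
  graphics::curve(stats::dlnorm(t, x$meanlog, x$sdlog), from = 0, to = upper,
                  xname = "t", xlab = "minutes", ylab = "density",
                  main = sprintf("lognormal fit to (%g, %g, %g)",
                                 x$spec$q1, x$spec$median, x$spec$q3), ...)
  graphics::abline(v = c(x$spec$q1, x$spec$median, x$spec$q3),
                   lty = c(3, 2, 3), col = "grey40")
  invisible(x)
}

#' Box plot of simulated turnaround times
#'
#' Mirrors the study's validation figure: box plots of registration and
#' clinic turnaround time per patient group, with the published medians
#' overlaid as reference points when supplied.
#'
#' @param x a `"replication_set"`.
#' @param reference optional named numeric vector of published medians with
#'   names among `reg_OBS`, `reg_GYN`, `reg_PRIVATE`, `clinic_OBS`,
#'   `clinic_GYN`, `clinic_PRIVATE`.
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
plot.replication_set <- function(x, reference = NULL, ...) {
  tt <- x$tt
  tt <- tt[tt$class %in% c("OBS", "GYN", "PRIVATE"), ]
  vals <- c(split(tt$registration_tt, paste0("reg_", tt$class)),
            split(tt$clinic_tt, paste0("clinic_", tt$class)))
  ord <- c("reg_OBS", "reg_GYN", "reg_PRIVATE",
           "clinic_OBS", "clinic_GYN", "clinic_PRIVATE")
  vals <- vals[ord[ord %in% names(vals)]]
  graphics::boxplot(vals, las = 2, ylab = "minutes",
                    main = sprintf("Turnaround times, scenario %s",
                                   x$scenario$id))
  if (!is.null(reference)) {
    at <- match(names(reference), names(vals))
    graphics::points(at, reference, pch = 18, cex = 1.6, col = "red3")
    graphics::legend("topright", legend = "published median", pch = 18,
                     col = "red3", bty = "n")
  }
  invisible(x)
}

#' Bar plot of percent change versus the base case
#'
#' @param x a `"scenario_comparison"`.
#' @param what `"tt"` (overall-TT change by patient group) or `"crowd"`
#'   (hourly crowd change).
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
plot.scenario_comparison <- function(x, what = c("tt", "crowd"), ...) {
  what <- match.arg(what)
  if (what == "tt") {
    graphics::barplot(x$tt_change, ylab = "% change in median overall TT",
                      main = sprintf("Scenario %s vs %s", x$scenario, x$base))
  } else {
    graphics::barplot(x$crowd_change, las = 2,
                      ylab = "% change in mean hourly crowd",
                      main = sprintf("Scenario %s vs %s", x$scenario, x$base))
  }
  graphics::abline(h = 0)
  invisible(x)
}
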