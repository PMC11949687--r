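# Base-graphics views of profiles, fits and predictive checks. These are
# working plots, not publication figures.

#' @export
plot.sim_profile <- function(x, ...) {
  ylim <- range(x$typical, x$lower95, x$upper95, na.rm = TRUE)
  plot(x$time_weeks, x$typical, type = "b", pch = 16, ylim = ylim,
       xlab = "time (weeks)",
       ylab = paste0(attr(x, "outcome"), " level"), ...)
  if (!is.null(x$lower95)) {
    graphics::polygon(c(x$time_weeks, rev(x$time_weeks)),
                      c(x$lower95, rev(x$upper95)),
                      col = grDevices::adjustcolor("steelblue", 0.25),
                      border = NA)
    graphics::lines(x$time_weeks, x$typical, type = "b", pch = 16)
  }
  invisible(x)
}

#' @export
plot.mbma <- function(x, ...) {
  pr <- predict(x)
  lim <- range(pr$observed, pr$predicted)
  plot(pr$predicted, pr$observed, pch = 16,
       cex = 0.4 + sqrt(pr$n) / 15, col = grDevices::adjustcolor(1, 0.6),
       xlim = lim, ylim = lim,
       xlab = "population-predicted decrease", ylab = "observed decrease",
       ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' @export
plot.mbma_vpc <- function(x, ...) {
  p <- x$percentiles
  ylim <- range(p$p2.5, p$p97.5, x$observed$observed)
  plot(NA, xlim = range(p$time_weeks), ylim = ylim,
       xlab = "time (weeks)", ylab = "decrease from baseline", ...)
  graphics::polygon(c(p$time_weeks, rev(p$time_weeks)),
                    c(p$p2.5, rev(p$p97.5)),
                    col = grDevices::adjustcolor("steelblue", 0.25),
                    border = NA)
  graphics::lines(p$time_weeks, p$p50, lwd = 2, col = "steelblue")
  graphics::points(x$observed$time_weeks, x$observed$observed,
                   pch = 16, cex = 0.4 + sqrt(x$observed$n) / 15,
                   col = grDevices::adjustcolor(1, 0.6))
  invisible(x)
}
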