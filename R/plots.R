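# Base-graphics displays of trajectories and load tables.

#' Plot a swelling trajectory
#'
#' Swelling (%) against time with closed-eye intervals (sleep, naps)
#' shaded.
#'
#' @param x An `edema_trajectory` from [simulate_day()] or
#'   [simulate_days()].
#' @param shade Shade closed-eye segments.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.edema_trajectory <- function(x, shade = TRUE, ...) {
  graphics::plot(x$time, x$swelling, type = "n",
                 xlab = "Time since sleep onset (h)",
                 ylab = "Corneal swelling (%)", ...)
  if (shade) {
    for (segname in c("overnight", "nap")) {
      idx <- x$segment == segname
      if (!any(idx)) next
      r <- range(x$time[idx])
      graphics::rect(r[1], graphics::par("usr")[3], r[2],
                     graphics::par("usr")[4],
                     col = if (segname == "overnight") "grey85" else
                       "grey93", border = NA)
    }
  }
  graphics::lines(x$time, x$swelling, lwd = 2)
  graphics::box()
  invisible(x)
}

#' Plot relative edema loads
#'
#' Grouped bar chart of relative loads by lens, one group per compliance
#' pattern, for a single wear duration.
#'
#' @param tab Output of [relative_load_table()] or
#'   [high_sweller_table()].
#' @param years Which wear duration (years) to display.
#' @param ... Passed to [graphics::barplot()].
#' @return The bar midpoints, invisibly.
#' @export
plot_relative_loads <- function(tab, years = 10, ...) {
  sub <- tab[tab$years == years, ]
  pat <- paste0(sub$naps_per_month, "n/", sub$sleeps_per_month, "s")
  m <- tapply(sub$relative_load, list(pat, sub$dkt_ipsi), mean)
  mids <- graphics::barplot(m, beside = TRUE, xlab = "Lens Dk/t",
                            ylab = sprintf("Relative edema load (%d y)",
                                           years),
                            legend.text = rownames(m), ...)
  invisible(mids)
}
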