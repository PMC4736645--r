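# PNG figure helpers (base graphics; colours are cosmetic).

#' Plot a cost sweep: steady-state distribution and mean per cost
#'
#' One column per cost: the pooled post-burn-in production distribution is
#' drawn as a vertical intensity strip with the pooled mean marked as a
#' diamond.
#'
#' @param sweep A [cost_sweep()] result.
#' @param path Optional PNG path; if `NULL`, draws on the current device.
#' @return `path` (or `NULL`), invisibly.
#' @export
plot_cost_sweep <- function(sweep, path = NULL) {
  stopifnot(inherits(sweep, "cost_sweep"))
  if (!is.null(path)) {
    grDevices::png(path, width = 720, height = 480)
    on.exit(grDevices::dev.off())
  }
  edges <- sweep$bin_edges
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  costs <- sweep$costs
  graphics::plot(NULL, xlim = range(costs) + c(-0.3, 0.3),
                 ylim = range(edges),
                 xlab = "cost per unit public good (c)",
                 ylab = "public good production (p)",
                 main = "steady-state production distribution by cost")
  wd <- if (length(costs) > 1) min(diff(sort(costs))) * 0.4 else 0.4
  for (i in seq_along(costs)) {
    d <- sweep$distributions[i, ]
    if (sum(d) == 0) next
    rel <- d / max(d)
    graphics::rect(costs[i] - wd, edges[-length(edges)],
                   costs[i] + wd, edges[-1],
                   col = grDevices::rgb(0.1, 0.3, 0.8, alpha = rel),
                   border = NA)
    graphics::points(costs[i], sweep$mean_p[i], pch = 18, cex = 1.6,
                     col = "red")
  }
  invisible(path)
}

#' Plot a time-resolved production distribution heat map
#'
#' @param result A `sim_result` (or trajectory data frame).
#' @param path Optional PNG path; if `NULL`, draws on the current device.
#' @param log_counts Intensity on `log1p` scale (helps when one mode
#'   dominates).
#' @return `path` (or `NULL`), invisibly.
#' @export
plot_heatmap <- function(result, path = NULL, log_counts = TRUE) {
  hm <- distribution_heatmap(result)
  if (!is.null(path)) {
    grDevices::png(path, width = 720, height = 480)
    on.exit(grDevices::dev.off())
  }
  z <- if (log_counts) log1p(hm) else hm
  tt <- as.numeric(rownames(hm))
  p_max <- if (inherits(result, "sim_result")) result$params$p_max else 10
  graphics::image(x = tt, y = seq(0, p_max, length.out = ncol(hm)), z = z,
                  col = grDevices::hcl.colors(64, "YlGnBu", rev = TRUE),
                  xlab = "Monte-Carlo step",
                  ylab = "public good production (p)",
                  main = "production distribution over time")
  invisible(path)
}
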