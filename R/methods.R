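# S3 methods for trial objects.

#' @export
print.iaif_trial <- function(x, ...) {
  cat(sprintf("IAIF trial: target %d (ID %.2f bits), %d steps, seed %d\n",
              x$target$index, x$target$id_bits, nrow(x$log), x$seed))
  cat(sprintf("  trigger mode: %s\n", x$agent_cfg$trigger$mode))
  cat(sprintf("  time on target: %.1f%%\n", time_on_target(x)))
  cat(sprintf("  planning phases: %d (div %d, efe %d, exhaustion %d)\n",
              count_planning_phases(x), count_fires(x, "div"),
              count_fires(x, "efe"), count_fires(x, "exhaustion")))
  cat(sprintf("  compute units: %d rollout steps\n", x$compute_units))
  invisible(x)
}

#' @export
summary.iaif_trial <- function(object, ...) {
  out <- trial_metrics(object)
  out$trigger_mode <- object$agent_cfg$trigger$mode
  out
}

#' Plot a trial trajectory
#'
#' Cursor position over time with the target band, the agent's believed
#' cursor position, and planning events marked at the top.
#'
#' @param x an `iaif_trial`.
#' @param ... passed to [plot()].
#' @export
plot.iaif_trial <- function(x, ...) {
  log <- x$log
  ylim <- range(c(log$s1_px, log$s3_px + log$s4_px, log$s3_px - log$s4_px))
  plot(log$time_s, log$s1_px, type = "l", col = "blue",
       xlab = "time (s)", ylab = "position (px)",
       ylim = ylim * 1.05, ...)
  graphics::polygon(c(log$time_s, rev(log$time_s)),
                    c(log$s3_px + log$s4_px, rev(log$s3_px - log$s4_px)),
                    col = grDevices::adjustcolor("red", 0.2), border = NA)
  graphics::lines(log$time_s, log$bel_pos_px, col = "darkgreen", lty = 2)
  ev <- log$time_s[log$planned]
  if (length(ev)) graphics::abline(v = ev, col = grDevices::adjustcolor("black", 0.25))
  graphics::legend("bottomright",
                   legend = c("cursor", "belief mean", "planning event"),
                   col = c("blue", "darkgreen", "grey40"),
                   lty = c(1, 2, 1), bty = "n", cex = 0.8)
  invisible(x)
}
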