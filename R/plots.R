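# Base-graphics views of simulation results.

arch_cols <- c(V = "#e75480", I = "#00bcd4", D = "#e6b800",
               unpatterned = "grey70")

#' Plot final 1D expression profiles
#'
#' @param x `trajectory_1d`.
#' @param time_hpf time to plot (default: final frame).
#' @param ... passed to `matplot`.
#' @return invisibly, the plotted matrix.
#' @export
plot.trajectory_1d <- function(x, time_hpf = max(x$times), ...) {
  i <- which.min(abs(x$times - time_hpf))
  st <- x$states[i, , ]
  graphics::matplot(x$positions, st, type = "l", lty = 1, lwd = 2,
                    col = arch_cols[GENES],
                    xlab = "D-V position (um, ventral = 0)",
                    ylab = "expression",
                    main = sprintf("%.1f hpf", x$times[i]), ...)
  graphics::legend("topright", legend = GENES, col = arch_cols[GENES],
                   lwd = 2, bty = "n")
  invisible(st)
}

#' Plot ensemble mean and +/- sigma bands
#'
#' @param x `ensemble_1d`.
#' @param time_hpf time to plot (default: final frame).
#' @param ... passed to `matplot`.
#' @return invisibly, the mean matrix.
#' @export
plot.ensemble_1d <- function(x, time_hpf = max(x$times), ...) {
  i <- which.min(abs(x$times - time_hpf))
  m <- x$mean[i, , ]; s <- x$sd[i, , ]
  graphics::matplot(x$positions, m, type = "n",
                    ylim = range(0, m + s),
                    xlab = "D-V position (um, ventral = 0)",
                    ylab = "expression",
                    main = sprintf("%.1f hpf, n = %d", x$times[i], x$n_runs),
                    ...)
  for (g in GENES) {
    graphics::polygon(c(x$positions, rev(x$positions)),
                      c(m[, g] + s[, g], rev(pmax(0, m[, g] - s[, g]))),
                      col = grDevices::adjustcolor(arch_cols[[g]], 0.25),
                      border = NA)
    graphics::lines(x$positions, m[, g], col = arch_cols[[g]], lwd = 2)
  }
  graphics::legend("topright", legend = GENES, col = arch_cols[GENES],
                   lwd = 2, bty = "n")
  invisible(m)
}

#' Plot a tissue frame with classified cells
#'
#' @param x `tissue_trajectory`.
#' @param time_hpf frame time (default: final).
#' @param reference_max classification reference (default: the run's own).
#' @param ... passed to `plot`.
#' @return invisibly, the label factor.
#' @export
plot.tissue_trajectory <- function(x, time_hpf = max(x$times),
                                   reference_max = tissue_reference_max(x),
                                   ...) {
  i <- which.min(abs(x$times - time_hpf))
  fr <- x$frames[[i]]
  lab <- classify(fr$states, reference_max)
  graphics::plot(rbind(fr$outline, fr$outline[1L, ]), type = "l",
                 asp = 1, xlab = "A-P (um)", ylab = "D-V (um)",
                 main = sprintf("%.1f hpf, %d cells", fr$t, nrow(fr$positions)),
                 ...)
  graphics::points(fr$positions, pch = 19, cex = 0.8,
                   col = arch_cols[as.character(lab)])
  invisible(lab)
}
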