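## Base-graphics plot methods for the analysis classes.

#' @export
plot.distance_series <- function(x, ..., col = "steelblue") {
  graphics::plot(x$time, x$value, type = "l", col = col,
                 xlab = if (length(x$boundaries))
                   "frame index (arbitrary reaction coordinate)"
                 else "time (ns)",
                 ylab = "distance (nm)", main = x$pair_label, ...)
  if (length(x$boundaries))
    graphics::abline(v = x$time[x$boundaries], lty = 3, col = "grey50")
  invisible(x)
}

#' @export
plot.occupancy_scan <- function(x, highlight = c(0.8, 0.9, 1.0), ...) {
  graphics::plot(NULL, xlim = range(x$d_grid), ylim = c(0, 1),
                 xlab = "d (nm)", ylab = "occupancy fraction",
                 main = "Mutually-exclusive occupancy", ...)
  hcol <- c("red", "blue", "darkgreen")
  for (i in seq_along(x$C)) {
    hit <- which(abs(highlight - x$C[i]) < 1e-9)
    graphics::lines(x$d_grid, x$fraction[i, ],
                    col = if (length(hit)) hcol[hit[1L]] else "grey75")
  }
  if (length(highlight))
    graphics::legend("topright", legend = sprintf("C = %.2f", highlight),
                     col = hcol[seq_along(highlight)], lty = 1, cex = 0.8)
  invisible(x)
}

#' @export
plot.dist_summary <- function(x, ...) {
  graphics::plot(x$kde_x, x$kde_y, type = "n", xlab = "distance (nm)",
                 ylab = "density (1/nm)", main = x$label, ...)
  graphics::rect(x$breaks[-length(x$breaks)], 0, x$breaks[-1L],
                 x$counts / (x$n * diff(x$breaks)[1L]),
                 col = "grey90", border = "grey60")
  graphics::lines(x$kde_x, x$kde_y, col = "firebrick", lwd = 2)
  m <- find_modes(x)
  if (nrow(m)) graphics::abline(v = m$location, lty = 3, col = "firebrick")
  invisible(x)
}

#' @export
plot.projection_cloud <- function(x, C = NULL, d = NULL, ...) {
  col <- rep("grey60", nrow(x))
  if (!is.null(C) && !is.null(d))
    col[flag_membership(x, C, d)] <- "red"
  graphics::plot(x$fefe_nm, x$femg_nm, pch = 16, cex = 0.3, col = col,
                 xlab = "Fe-Fe distance (nm)", ylab = "Fe-Mg distance (nm)",
                 main = "Two-vector projection", ...)
  invisible(x)
}

#' @export
plot.flex_profile <- function(x, ...) {
  graphics::plot(x$resno, x$rmsf, type = "h", lwd = 3, col = "steelblue",
                 xlab = "residue", ylab = "RMSF (nm)",
                 main = "Per-residue RMSF", ...)
  invisible(x)
}
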