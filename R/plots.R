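# Decorative base-graphics summaries; nothing downstream depends on them.

#' Plot colour loci
#'
#' Hexagon model: loci inside the unit colour hexagon. Fly model: loci
#' inside the [-1, 1]^2 opponent square with its quadrant boundaries.
#'
#' @param loci a [colour_loci()] table for a single model.
#' @param ... passed to [graphics::points()].
#' @export
plot_loci <- function(loci, ...) {
  model <- unique(loci$model)
  stopifnot(length(model) == 1)
  if (model == "hexagon") {
    ang <- seq(30, 390, by = 60) * pi / 180
    plot(cos(ang), sin(ang), type = "l", asp = 1, xlab = "x (EU)",
         ylab = "y (EU)", main = "bee colour hexagon")
  } else {
    plot(NA, xlim = c(-1, 1), ylim = c(-1, 1), asp = 1, xlab = "x",
         ylab = "y", main = "fly colour space")
    graphics::abline(h = 0, v = 0, lty = 3)
  }
  cls <- factor(loci$group)
  graphics::points(loci$x, loci$y, col = as.integer(cls) + 1, pch = 19, ...)
  graphics::legend("topright", legend = levels(cls),
                   col = seq_along(levels(cls)) + 1, pch = 19, cex = 0.7)
  invisible(loci)
}

#' Plot binned marker-point frequencies
#'
#' @param bins a [bin_marker_points()] table (optionally grouped).
#' @export
plot_marker_bins <- function(bins) {
  groups <- if ("group" %in% names(bins)) unique(bins$group) else NA
  graphics::par(mfrow = c(length(groups), 1), mar = c(3, 4, 2, 1))
  for (g in groups) {
    b <- if (is.na(g[1])) bins else bins[bins$group == g, ]
    graphics::barplot(b$rel_freq, names.arg = b$bin_lo, las = 2,
                      ylab = "rel. freq.", main = if (is.na(g[1])) "" else g)
    graphics::abline(v = c(400, 500), lty = 3)
  }
  invisible(bins)
}
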