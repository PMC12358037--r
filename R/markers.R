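# Spectral marker points: sharp reflectance transitions, their wavelength
# distribution, and fit metrics against pollinator discrimination optima.

#' Marker-point detector settings
#'
#' Defaults follow the recommended settings of the published detector this
#' module re-implements: reflectance changes of at least 10 percentage
#' points over a 50 nm window, a smoothing window of +/-10 data points, and
#' 5 data points of lookahead for the slope.
#'
#' @param min_change minimum reflectance change; percentage points when
#'   `relative = FALSE` (default), percent of the window maximum otherwise.
#' @param window_nm wavelength span (nm) over which the change criterion is
#'   evaluated; must be at least one grid step.
#' @param smooth_halfwidth half-width of the centred moving-average smoother,
#'   in data points.
#' @param lookahead forward-difference distance for the slope, in data points.
#' @param relative interpret `min_change` as a relative change.
#' @return an object of class `marker_settings`.
#' @export
marker_settings <- function(min_change = 10, window_nm = 50,
                            smooth_halfwidth = 10, lookahead = 5,
                            relative = FALSE) {
  stopifnot(min_change > 0, window_nm > 0, smooth_halfwidth > 0, lookahead > 0)
  structure(list(min_change = min_change, window_nm = window_nm,
                 smooth_halfwidth = as.integer(smooth_halfwidth),
                 lookahead = as.integer(lookahead), relative = relative),
            class = "marker_settings")
}

#' Detect spectral marker points
#'
#' Finds the wavelengths of sharp reflectance transitions in each spectrum.
#' The spectrum is smoothed with a centred moving average of
#' `+/-smooth_halfwidth` points, the slope is taken as a forward difference
#' over `lookahead` points, and candidate marker points are local maxima of
#' the absolute slope (placed at the centre of the lookahead interval). A
#' candidate is accepted iff the reflectance range (max minus min of the
#' smoothed curve) within `window_nm` centred on it reaches `min_change`;
#' windows are truncated at the grid ends. Accepted points closer together
#' than `window_nm / 2` are merged to the one with the steepest slope, so no
#' two reported points are closer than half the window.
#'
#' @param ss a `spec_set`.
#' @param cfg a [marker_settings()].
#' @return a list (class `marker_sets`) of one `marker_points` object per
#'   spectrum: list with `label`, `points_nm` (sorted, possibly empty) and
#'   `slopes` (percent per nm at each point).
#' @export
detect_marker_points <- function(ss, cfg = marker_settings()) {
  stopifnot(inherits(ss, "spec_set"), inherits(cfg, "marker_settings"))
  step <- grid_step(ss$wl)
  if (cfg$window_nm < step) stop("window_nm must be at least one grid step", call. = FALSE)
  n <- length(ss$wl)
  if (n <= 2 * cfg$smooth_halfwidth + 1) {
    stop("spectrum shorter than the smoothing window", call. = FALSE)
  }
  out <- lapply(labels(ss), function(lab) {
    mp <- detect_one(ss$wl, ss$refl[, lab], cfg, step)
    structure(list(label = lab, points_nm = mp$points, slopes = mp$slopes),
              class = "marker_points")
  })
  names(out) <- labels(ss)
  structure(out, class = c("marker_sets", "list"))
}

detect_one <- function(wl, y, cfg, step) {
  sm <- moving_mean(y, cfg$smooth_halfwidth)
  n <- length(wl)
  la <- cfg$lookahead
  idx <- seq_len(n - la)
  slope <- (sm[idx + la] - sm[idx]) / (la * step)
  a <- abs(slope)
  m <- length(a)
  is_max <- a > 1e-8 &
    a >= c(Inf, a[-m]) &   # not below the left neighbour (left edge excluded)
    a > c(a[-1], -Inf)     # strictly above the right neighbour
  cand <- which(is_max)
  if (!length(cand)) return(list(points = numeric(0), slopes = numeric(0)))
  # place the point at the centre of the lookahead interval
  lam <- wl[cand] + la * step / 2
  half <- cfg$window_nm / 2
  keep <- vapply(lam, function(l) {
    win <- sm[wl >= l - half & wl <= l + half]
    rng <- max(win) - min(win)
    if (cfg$relative) rng >= cfg$min_change / 100 * max(win) else rng >= cfg$min_change
  }, logical(1))
  lam <- lam[keep]; sl <- slope[cand][keep]
  if (!length(lam)) return(list(points = numeric(0), slopes = numeric(0)))
  # merge points closer than window/2, keeping the steepest
  ord <- order(abs(sl), decreasing = TRUE)
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(lam[i] - lam[kept]) >= half)) kept <- c(kept, i)
  }
  o <- order(lam[kept])
  list(points = lam[kept][o], slopes = sl[kept][o])
}

#' @export
print.marker_points <- function(x, ...) {
  cat(sprintf("<marker_points> %s: %s\n", x$label,
              if (length(x$points_nm)) paste(round(x$points_nm, 1), collapse = "; ")
              else "(none)"))
  invisible(x)
}

#' Bin marker points into wavelength classes
#'
#' Tallies marker points from a collection of spectra into half-open
#' wavelength bins `[lo, lo + binwidth)` spanning 300--700 nm and reports
#' relative frequencies (summing to 1 over all points of the non-empty
#' sets). With `groups`, frequencies are computed within each group.
#'
#' @param mps a `marker_sets` list from [detect_marker_points()].
#' @param binwidth bin width in nm; must divide the 400 nm range.
#' @param groups optional named vector mapping spectrum labels to groups.
#' @return data.frame `bin_lo, bin_hi, count, rel_freq[, group]`; zero rows
#'   (with a warning) if no points exist at all.
#' @export
bin_marker_points <- function(mps, binwidth = 10, groups = NULL) {
  stopifnot(binwidth > 0, 400 %% binwidth == 0)
  breaks <- seq(300, 700, by = binwidth)
  tally <- function(points) {
    if (!length(points)) {
      return(data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
                        count = 0L, rel_freq = NA_real_)[0, ])
    }
    idx <- pmin(floor((points - 300) / binwidth) + 1L, length(breaks) - 1L)
    cnt <- tabulate(idx, nbins = length(breaks) - 1L)
    data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
               count = cnt, rel_freq = cnt / sum(cnt))
  }
  if (is.null(groups)) {
    pts <- unlist(lapply(mps, `[[`, "points_nm"), use.names = FALSE)
    out <- tally(pts)
    if (!nrow(out)) warning("no marker points in any spectrum", call. = FALSE)
    return(out)
  }
  out <- do.call(rbind, lapply(unique(unname(groups)), function(g) {
    labs <- names(groups)[groups == g]
    pts <- unlist(lapply(mps[intersect(labs, names(mps))], `[[`, "points_nm"),
                  use.names = FALSE)
    tb <- tally(pts)
    if (nrow(tb)) tb$group <- g
    tb
  }))
  if (is.null(out) || !nrow(out)) warning("no marker points in any spectrum", call. = FALSE)
  out
}

#' Minimal absolute deviation from a discrimination optimum
#'
#' The minimum distance (nm) between any marker point of a spectrum and one
#' wavelength of optimal visual discrimination. Undefined (error) for
#' spectra without marker points; such species are excluded from summaries.
#'
#' @param mp a `marker_points` object or a numeric vector of wavelengths.
#' @param optimum discrimination-optimum wavelength (nm).
#' @return distance in nm.
#' @export
min_abs_deviation <- function(mp, optimum) {
  points <- if (inherits(mp, "marker_points")) mp$points_nm else mp
  if (!length(points)) {
    stop("minAD undefined: the spectrum has no marker points", call. = FALSE)
  }
  min(abs(points - optimum))
}

#' Mean absolute deviation from discrimination optima
#'
#' The average proximity of a spectrum's marker points to the wavelengths of
#' maximum discrimination. Under the default `"nearest"` definition each
#' marker point contributes its distance to the nearest optimum; the
#' `"all_pairs"` variant averages over every point-optimum pair.
#'
#' @param mp a `marker_points` object or numeric vector of wavelengths.
#' @param optima numeric vector of optimum wavelengths (nm), e.g. the bee
#'   optima `c(400, 500)`.
#' @param method `"nearest"` (default) or `"all_pairs"`.
#' @return deviation in nm.
#' @export
mean_abs_deviation <- function(mp, optima, method = c("nearest", "all_pairs")) {
  method <- match.arg(method)
  points <- if (inherits(mp, "marker_points")) mp$points_nm else mp
  if (!length(points)) {
    stop("MAD undefined: the spectrum has no marker points", call. = FALSE)
  }
  d <- abs(outer(points, optima, `-`))
  if (method == "nearest") mean(apply(d, 1, min)) else mean(d)
}

#' Marker-point fit metrics for a set of spectra
#'
#' MAD and per-optimum minAD for every spectrum with at least one marker
#' point; spectra without marker points get `NA` rows and are listed in the
#' `excluded` attribute.
#'
#' @param mps a `marker_sets` list.
#' @param optima optimum wavelengths (nm); default the bee optima 400 and
#'   500 nm. Non-bee taxa must supply their own list.
#' @param method MAD definition, see [mean_abs_deviation()].
#' @return data.frame `label, n_points, MAD, minAD_<optimum>...` with
#'   attribute `excluded` (labels without marker points).
#' @export
marker_metrics <- function(mps, optima = c(400, 500),
                           method = c("nearest", "all_pairs")) {
  method <- match.arg(method)
  rows <- lapply(mps, function(mp) {
    n <- length(mp$points_nm)
    if (n == 0) {
      vals <- c(MAD = NA_real_,
                stats::setNames(rep(NA_real_, length(optima)),
                                paste0("minAD_", optima)))
    } else {
      vals <- c(MAD = mean_abs_deviation(mp, optima, method),
                stats::setNames(vapply(optima, function(o) min_abs_deviation(mp, o),
                                       numeric(1)),
                                paste0("minAD_", optima)))
    }
    data.frame(label = mp$label, n_points = n, t(vals), check.names = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "excluded") <- out$label[out$n_points == 0]
  out
}
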