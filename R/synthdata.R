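# Pigment-based synthetic reflectance spectra, trees and trait datasets:
# the generator that lets the whole workflow run and be calibrated without
# field measurements.

#' Pigment absorption band
#'
#' A Gaussian absorbance band: `strength * exp(-(wl - centre)^2 / (2 width^2))`.
#'
#' @param centre band centre (nm).
#' @param width Gaussian standard deviation (nm), `> 0`.
#' @param strength absorbance at the centre, `>= 0`; a length-2 vector gives
#'   a uniform sampling range for stochastic presets.
#' @return a `pigment_band` list.
#' @export
pigment_band <- function(centre, width, strength) {
  stopifnot(width > 0, all(strength >= 0), length(strength) %in% 1:2)
  if (length(strength) == 1) strength <- c(strength, strength)
  structure(list(centre = centre, width = width, strength = strength),
            class = "pigment_band")
}

# Common band positions (literature-style): chlorophyll a ~430/670 nm,
# chlorophyll b ~455/645 nm, a carotenoid triplet ~425/450/480 nm, a
# cyanidin-type anthocyanin ~530 nm (~560 nm for blue-violet copigmented
# forms), and a broad UV absorber (flavonol-type) ~330 nm.
chl_a_bands <- function(s) list(pigment_band(430, 30, s), pigment_band(670, 25, s))
chl_b_bands <- function(s) list(pigment_band(455, 25, s), pigment_band(645, 25, s))
carotenoid_bands <- function(s) list(pigment_band(425, 20, s),
                                     pigment_band(450, 20, s),
                                     pigment_band(480, 22, s))
uv_band <- function(s) list(pigment_band(330, 55, s))

#' Flower colour-class presets
#'
#' Pigment mixes emulating the six human-perceived colour classes of the
#' study design plus the green-foliage background. Green flowers share the
#' foliage pigments (chlorophylls + carotenoids) at flower-specific
#' concentrations; green-yellow flowers carry less chlorophyll and more
#' carotenoid, suppressing 400--500 nm reflectance and elevating the
#' long-wavelength plateau; the comparison classes (blue-violet, pink,
#' white, yellow) use anthocyanin/carotenoid mixes. Strength entries with a
#' range are drawn uniformly per spectrum; the foliage preset is fully
#' deterministic so it can serve as the adaptation background.
#'
#' @return named list of presets, each a list with `class_name`, `baseline`
#'   (maximal reflectance, percent; range), `bands` (list of
#'   [pigment_band()]), `noise_sd` (percent) and `noise_bw` (nm).
#' @export
flower_presets <- function() {
  mk <- function(class_name, baseline, bands, noise_sd = 0.8, noise_bw = 15) {
    if (length(baseline) == 1) baseline <- c(baseline, baseline)
    list(class_name = class_name, baseline = baseline, bands = bands,
         noise_sd = noise_sd, noise_bw = noise_bw)
  }
  list(
    foliage = mk("foliage", 18,
                 c(uv_band(2.0), chl_a_bands(1.2), chl_b_bands(0.6),
                   list(pigment_band(610, 45, 0.55)),
                   carotenoid_bands(0.5)),
                 noise_sd = 0),
    green = mk("green", c(12, 55),
               c(uv_band(c(1.9, 2.9)),
                 list(pigment_band(430, 30, c(0.9, 1.8)),
                      pigment_band(670, 25, c(0.9, 1.8)),
                      pigment_band(455, 25, c(0.45, 0.9)),
                      pigment_band(645, 25, c(0.45, 0.9)),
                      pigment_band(610, 45, c(0.4, 0.75))),
                 carotenoid_bands(c(0.35, 1.1)))),
    green_yellow = mk("green_yellow", c(22, 34),
                      c(uv_band(c(2.4, 3.2)),
                        list(pigment_band(430, 30, c(0.4, 1.0)),
                             pigment_band(670, 25, c(0.4, 1.0)),
                             pigment_band(455, 25, c(0.2, 0.5)),
                             pigment_band(645, 25, c(0.2, 0.5)),
                             pigment_band(610, 45, c(0.15, 0.35))),
                        carotenoid_bands(c(3.2, 4.5)))),
    blue_violet = mk("blue_violet", c(40, 60),
                     c(uv_band(c(1.5, 3.0)),
                       list(pigment_band(560, 55, c(2.0, 3.5)),
                            pigment_band(670, 25, c(0.2, 0.6))))),
    pink = mk("pink", c(45, 65),
              c(uv_band(c(1.5, 3.0)),
                list(pigment_band(530, 45, c(1.5, 2.5))))),
    white = mk("white", c(55, 80), uv_band(c(2.0, 3.0))),
    yellow = mk("yellow", c(45, 70),
                c(uv_band(c(1.8, 3.0)), carotenoid_bands(c(2.5, 4.0))))
  )
}

# smooth correlated noise: Gaussian-kernel-smoothed white noise rescaled to
# the requested sd, so it does not create spurious marker points
smooth_noise <- function(wl, sd, bw) {
  if (sd <= 0) return(rep(0, length(wl)))
  z <- stats::rnorm(length(wl))
  W <- exp(-outer(wl, wl, `-`)^2 / (2 * bw^2))
  s <- drop(W %*% z) / rowSums(W)
  s / stats::sd(s) * sd
}

#' Generate one synthetic reflectance spectrum
#'
#' Beer-Lambert style pigment model:
#' `R(wl) = baseline * exp(-sum(bands))` plus smooth low-amplitude noise,
#' clipped to `[0, 100]` percent. Baseline and band strengths with ranges
#' are drawn uniformly (seeded).
#'
#' @param preset a preset list from [flower_presets()], or the name of one.
#' @param seed optional integer seed; with `NULL` the current RNG stream is
#'   used (so callers can seed a whole set at once).
#' @param grid wavelength grid.
#' @param label spectrum label; defaults to the class name.
#' @return a single-spectrum [spec_set()] with the class as its group.
#' @export
make_spectrum <- function(preset, seed = NULL, grid = wl_grid(), label = NULL) {
  if (is.character(preset)) preset <- flower_presets()[[preset]]
  if (is.null(preset)) stop("unknown preset", call. = FALSE)
  gen <- function() {
    baseline <- stats::runif(1, preset$baseline[1], preset$baseline[2])
    A <- rep(0, length(grid))
    for (b in preset$bands) {
      s <- stats::runif(1, b$strength[1], b$strength[2])
      A <- A + s * exp(-(grid - b$centre)^2 / (2 * b$width^2))
    }
    r <- baseline * exp(-A) + smooth_noise(grid, preset$noise_sd, preset$noise_bw)
    pmin(pmax(r, 0), 100)
  }
  r <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  lab <- label %||% preset$class_name
  spec_set(grid, r, labels = lab,
           groups = stats::setNames(preset$class_name, lab))
}

#' Synthetic green-foliage background
#'
#' The deterministic foliage-preset spectrum: low UV and blue reflectance, a
#' green peak near 550 nm and the chlorophyll valley at ~670 nm. Used as the
#' default adaptation background of [viewing_context()]; a measured foliage
#' spectrum can be supplied there instead for literature comparability.
#'
#' @param grid wavelength grid.
#' @return a single-spectrum `spec_set` labelled `"foliage"`.
#' @export
foliage_background <- function(grid = wl_grid()) {
  make_spectrum("foliage", grid = grid, label = "foliage")
}

#' Generate the default synthetic study set
#'
#' A labelled, grouped set of synthetic flower spectra. The default class
#' counts mirror the study design the generator emulates: green 19,
#' green-yellow 11, plus the comparison classes yellow 38, blue-violet 28,
#' pink 25 and white 9 (130 spectra).
#'
#' @param n_per_class named integer vector of spectra per class; names must
#'   be preset names.
#' @param seed integer seed; the same seed reproduces the identical set.
#' @param grid wavelength grid.
#' @return a [spec_set()] with `groups` set.
#' @export
make_study_set <- function(n_per_class = c(green = 19, green_yellow = 11,
                                           blue_violet = 28, pink = 25,
                                           white = 9, yellow = 38),
                           seed = 1, grid = wl_grid()) {
  stopifnot(all(n_per_class >= 0), !is.null(names(n_per_class)))
  presets <- flower_presets()
  unknown <- setdiff(names(n_per_class), names(presets))
  if (length(unknown)) stop("unknown classes: ", paste(unknown, collapse = ", "),
                            call. = FALSE)
  build <- function() {
    cols <- list(); grp <- character(0)
    for (cls in names(n_per_class)) {
      for (i in seq_len(n_per_class[[cls]])) {
        lab <- sprintf("%s_%02d", cls, i)
        cols[[lab]] <- make_spectrum(presets[[cls]], grid = grid, label = lab)$refl[, 1]
        grp[lab] <- cls
      }
    }
    spec_set(grid, do.call(cbind, cols), labels = names(cols), groups = grp)
  }
  withr::with_seed(seed, build())
}

#' Simulate an ultrametric pure-birth tree
#'
#' A Yule (pure-birth) tree used as a stand-in phylogeny for the
#' statistical machinery; ultrametric by construction.
#'
#' @param n_tips number of tips, `>= 2`.
#' @param seed integer seed.
#' @param labels optional tip labels (length `n_tips`).
#' @return an `ape::phylo` tree.
#' @export
make_yule_tree <- function(n_tips, seed = 1, labels = NULL) {
  if (n_tips < 2) stop("n_tips must be >= 2", call. = FALSE)
  tr <- withr::with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  if (!is.null(labels)) {
    stopifnot(length(labels) == n_tips)
    tr$tip.label <- labels
  }
  tr
}

#' Simulate a trait dataset on a tree
#'
#' Brownian tip values plus fixed group mean shifts: the input for power and
#' type-I-error experiments with [phyl_anova()]. `shifts = 0` everywhere
#' gives a null dataset.
#'
#' @param tree an `ape::phylo` tree.
#' @param group_map named character vector mapping tip labels to groups.
#' @param sigma2 Brownian rate.
#' @param shifts named numeric vector of group mean offsets (defaults to 0
#'   for groups not named).
#' @param seed optional integer seed.
#' @return data.frame `label, value, group`.
#' @export
make_trait_dataset <- function(tree, group_map, sigma2, shifts = NULL,
                               seed = NULL) {
  tips <- tree$tip.label
  if (!all(tips %in% names(group_map))) {
    stop("every tip needs a group in group_map", call. = FALSE)
  }
  grp <- group_map[tips]
  if (!is.null(shifts)) {
    unknown <- setdiff(names(shifts), unique(grp))
    if (length(unknown)) stop("shifts name unknown groups: ",
                              paste(unknown, collapse = ", "), call. = FALSE)
  }
  x <- simulate_bm(tree, sigma2, nsim = 1, seed = seed)[, 1]
  off <- if (is.null(shifts)) rep(0, length(tips)) else {
    s <- stats::setNames(rep(0, length(unique(grp))), unique(grp))
    s[names(shifts)] <- shifts
    s[grp]
  }
  data.frame(label = tips, value = unname(x + off), group = unname(grp))
}
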