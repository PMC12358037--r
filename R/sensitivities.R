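# Receptor spectral sensitivities and the illuminant.

#' Visual-pigment nomogram template
#'
#' Evaluates the Govardovskii A1 visual-pigment template (alpha plus beta
#' band) at the given wavelengths for a pigment with the given peak
#' wavelength. Used to build receptor sensitivity curves when no tabulated
#' curve is supplied.
#'
#' @param wl wavelengths (nm).
#' @param lambda_max peak wavelength of the pigment (nm).
#' @return relative sensitivity (not yet peak-normalized on the grid).
#' @references Govardovskii et al. (2000) Visual Neuroscience 17:509-528.
#' @export
pigment_template <- function(wl, lambda_max) {
  x <- lambda_max / wl
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  S_alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                    exp(-14.9 * (1.104 - x)) + 0.674)
  lam_beta <- 189 + 0.315 * lambda_max
  b_beta <- -40.5 + 0.195 * lambda_max
  S_beta <- 0.26 * exp(-((wl - lam_beta) / b_beta)^2)
  S_alpha + S_beta
}

#' Build a receptor sensitivity curve
#'
#' Either evaluates the visual-pigment nomogram template at `lambda_max` on
#' the grid, or wraps a user-supplied tabulated curve. The curve is
#' peak-normalized to 1.
#'
#' @param lambda_max peak wavelength (nm); required for the nomogram
#'   template, must lie on the grid range.
#' @param template `"nomogram"` (default) or `"tabulated"`.
#' @param curve numeric sensitivity values on `grid` (tabulated template).
#' @param grid wavelength grid; see [wl_grid()].
#' @param name receptor label.
#' @return an object of class `receptor`: list with `name`, `lambda_max`,
#'   `wl` and peak-normalized `curve`.
#' @export
make_receptor <- function(lambda_max = NULL,
                          template = c("nomogram", "tabulated"),
                          curve = NULL, grid = wl_grid(), name = NULL) {
  template <- match.arg(template)
  if (template == "nomogram") {
    if (is.null(lambda_max) || lambda_max < min(grid) || lambda_max > max(grid)) {
      stop("lambda_max must lie within the wavelength grid", call. = FALSE)
    }
    curve <- pigment_template(grid, lambda_max)
  } else {
    if (is.null(curve) || length(curve) != length(grid)) {
      stop("tabulated template needs a curve on the grid", call. = FALSE)
    }
    if (any(curve < 0)) stop("sensitivity curve must be non-negative", call. = FALSE)
    if (is.null(lambda_max)) lambda_max <- grid[which.max(curve)]
  }
  curve <- curve / max(curve)
  structure(list(name = name %||% sprintf("r%g", lambda_max),
                 lambda_max = lambda_max, wl = grid, curve = curve),
            class = "receptor")
}

#' @export
print.receptor <- function(x, ...) {
  cat(sprintf("<receptor> %s, lambda_max = %g nm\n", x$name, x$lambda_max))
  invisible(x)
}

#' Honeybee receptor set
#'
#' The trichromatic receptor set of *Apis mellifera* (UV, blue, green) built
#' from the pigment nomogram with literature peak wavelengths. The peaks are
#' editable so any convention can be reproduced; tabulated curves can be
#' supplied through [make_receptor()] instead.
#'
#' @param grid wavelength grid.
#' @param lambda_max named peaks (nm), in the order UV, blue, green.
#' @return list of three `receptor` objects.
#' @export
bee_receptors <- function(grid = wl_grid(),
                          lambda_max = c(uv = 344, blue = 436, green = 544)) {
  stopifnot(length(lambda_max) == 3)
  if (is.null(names(lambda_max))) names(lambda_max) <- c("uv", "blue", "green")
  mapply(function(lm, nm) make_receptor(lm, grid = grid, name = nm),
         lambda_max, names(lambda_max), SIMPLIFY = FALSE)
}

#' Blowfly receptor set
#'
#' The four receptor classes of the tetravariant *Lucilia*-type fly visual
#' system (pale and yellow R7/R8 cells), built from the pigment nomogram with
#' literature-style peak wavelengths; editable like [bee_receptors()].
#'
#' @param grid wavelength grid.
#' @param lambda_max named peaks (nm), in the order R7p, R7y, R8p, R8y.
#' @return list of four `receptor` objects.
#' @export
fly_receptors <- function(grid = wl_grid(),
                          lambda_max = c(R7p = 335, R7y = 355,
                                         R8p = 460, R8y = 530)) {
  stopifnot(length(lambda_max) == 4)
  if (is.null(names(lambda_max))) names(lambda_max) <- c("R7p", "R7y", "R8p", "R8y")
  mapply(function(lm, nm) make_receptor(lm, grid = grid, name = nm),
         lambda_max, names(lambda_max), SIMPLIFY = FALSE)
}

# CIE standard illuminant D65, relative spectral power at 10 nm intervals,
# 300-700 nm.
d65_table <- data.frame(
  wl = seq(300, 700, by = 10),
  power = c(0.0341, 3.2945, 20.236, 37.0535, 39.9488, 44.9117, 46.6383,
            52.0891, 49.9755, 54.6482, 82.7549, 91.486, 93.4318, 86.6823,
            104.865, 117.008, 117.812, 114.861, 115.923, 108.811, 109.354,
            107.802, 104.79, 107.689, 104.405, 104.046, 100, 96.3342,
            95.788, 88.6856, 90.0062, 89.5991, 87.6987, 83.2886, 83.6992,
            80.0268, 80.2146, 82.2778, 78.2842, 69.7213, 71.6091)
)

#' Standard daylight illuminant (D65)
#'
#' CIE standard illuminant D65 interpolated onto the grid and normalized to
#' unit mean irradiance. Under von Kries adaptation the absolute scale of the
#' illuminant cancels, so only the spectral shape matters.
#'
#' @param grid wavelength grid.
#' @return an object of class `illuminant`: list with `name`, `wl`,
#'   `irradiance`.
#' @export
illuminant_d65 <- function(grid = wl_grid()) {
  irr <- stats::approx(d65_table$wl, d65_table$power, xout = grid,
                       method = "linear", rule = 2)$y
  irr <- irr / mean(irr)
  structure(list(name = "D65", wl = grid, irradiance = irr),
            class = "illuminant")
}

#' Flat (equal-energy) illuminant
#'
#' @param grid wavelength grid.
#' @return an `illuminant` with unit irradiance everywhere.
#' @export
illuminant_flat <- function(grid = wl_grid()) {
  structure(list(name = "flat", wl = grid,
                 irradiance = rep(1, length(grid))),
            class = "illuminant")
}

#' Read a tabulated illuminant from delimited text
#'
#' Wide dialect: `wavelength_nm` plus one irradiance column. Normalized to
#' unit mean.
#'
#' @param path file path.
#' @param grid wavelength grid.
#' @return an `illuminant`.
#' @export
read_illuminant <- function(path, grid = wl_grid()) {
  ss <- read_spectra(path, dialect = "wide", grid = grid)
  irr <- ss$refl[, 1]
  if (any(irr < 0)) stop("irradiance must be non-negative", call. = FALSE)
  structure(list(name = colnames(ss$refl)[1], wl = grid,
                 irradiance = irr / mean(irr)),
            class = "illuminant")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
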