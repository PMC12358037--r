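# Colour-vision models: quantum catches, von Kries adaptation, the bee
# colour hexagon and the tetravariant fly colour space.

#' Default discriminability thresholds (EU)
#'
#' Empirical chromatic-contrast thresholds: 0.11 EU for the honeybee colour
#' hexagon and 0.096 EU for the fly colour space (established for
#' *Apis mellifera* and *Eristalis tenax* respectively). Stimuli at exactly
#' the threshold count as discriminable.
#' @export
default_thresholds <- c(hexagon = 0.11, fly = 0.096)

hexagon_sectors <- c("blue_green", "blue", "uv_blue", "uv", "uv_green", "green")

#' Default fly quadrant labels
#'
#' Maps the sign pair of the opponent coordinates (x, y) to the four
#' categorical fly colours. Keys are `"x>=0"`/`"x<0"` crossed with
#' `"y>=0"`/`"y<0"` written as e.g. `"+-"` (x sign then y sign). The default
#' places "yellow" in the quadrant reached by long-wavelength-dominant
#' spectra under the default receptor curves and foliage background (checked
#' by a built-in smoke test with a 580 nm narrowband stimulus).
#' @export
fly_quadrants_default <- c("++" = "uv", "-+" = "blue",
                           "--" = "purple", "+-" = "yellow")

#' Viewing context
#'
#' Bundles everything needed to map a reflectance spectrum to a colour
#' locus: the receptor set, the illuminant, the adaptation background and
#' the colour-space model. Defaults: honeybee receptors / fly receptors from
#' the pigment nomogram, D65 illuminant, and the synthetic green-foliage
#' background from [foliage_background()].
#'
#' @param model `"hexagon"` (trichromatic bee colour hexagon) or `"fly"`
#'   (tetravariant fly colour space).
#' @param receptors list of `receptor` objects; 3 for the hexagon (UV, blue,
#'   green order), 4 for the fly model (R7p, R7y, R8p, R8y order).
#' @param illuminant an `illuminant`; default D65.
#' @param background a single-spectrum [spec_set()]; default synthetic green
#'   foliage. Must give a strictly positive quantum catch in every receptor.
#' @param threshold chromatic discriminability threshold (EU); defaults per
#'   model from [default_thresholds].
#' @param quadrant_map fly model only: sign-pair to colour-category mapping;
#'   see [fly_quadrants_default].
#' @return an object of class `viewing_context`.
#' @export
viewing_context <- function(model = c("hexagon", "fly"),
                            receptors = NULL, illuminant = NULL,
                            background = NULL, threshold = NULL,
                            quadrant_map = fly_quadrants_default) {
  model <- match.arg(model)
  grid <- if (!is.null(illuminant)) illuminant$wl else wl_grid()
  receptors <- receptors %||%
    (if (model == "hexagon") bee_receptors(grid) else fly_receptors(grid))
  n_exp <- if (model == "hexagon") 3L else 4L
  if (length(receptors) != n_exp) {
    stop(sprintf("%s model needs exactly %d receptors", model, n_exp), call. = FALSE)
  }
  illuminant <- illuminant %||% illuminant_d65(grid)
  background <- background %||% foliage_background(grid)
  stopifnot(inherits(background, "spec_set"))
  if (length(background) != 1) background <- background[1]
  ctx <- structure(
    list(model = model, receptors = receptors, illuminant = illuminant,
         background = background,
         threshold = threshold %||% unname(default_thresholds[model]),
         quadrant_map = quadrant_map),
    class = "viewing_context")
  ctx$bg_catch <- receptor_catches(background, ctx)[1, ]
  if (any(ctx$bg_catch <= 0)) {
    stop("background must give a strictly positive catch in every receptor",
         call. = FALSE)
  }
  ctx
}

#' @export
print.viewing_context <- function(x, ...) {
  cat(sprintf("<viewing_context> model=%s, illuminant=%s, threshold=%g EU\n",
              x$model, x$illuminant$name, x$threshold))
  cat("  receptors:",
      paste(vapply(x$receptors, function(r) sprintf("%s(%g)", r$name, r$lambda_max),
                   character(1)), collapse = ", "), "\n")
  invisible(x)
}

#' Receptor quantum catch
#'
#' The photon signal a receptor class absorbs from a stimulus: the integral
#' of reflectance x sensitivity x illuminant over wavelength, computed by
#' the rectangle rule on the shared grid. Reflectance enters as a fraction
#' (internal percent scale divided by 100).
#'
#' @param s a `spec_set` (one or more spectra).
#' @param r a `receptor`.
#' @param i an `illuminant`.
#' @return numeric vector of catches, one per spectrum.
#' @export
quantum_catch <- function(s, r, i) {
  stopifnot(inherits(s, "spec_set"), inherits(r, "receptor"),
            inherits(i, "illuminant"))
  if (length(s$wl) != length(r$wl) || any(abs(s$wl - r$wl) > 1e-9) ||
      any(abs(s$wl - i$wl) > 1e-9)) {
    stop("spectrum, receptor and illuminant must share one grid", call. = FALSE)
  }
  step <- grid_step(s$wl)
  drop(crossprod(s$refl / 100, r$curve * i$irradiance)) * step
}

receptor_catches <- function(s, ctx) {
  out <- vapply(ctx$receptors, function(r) quantum_catch(s, r, ctx$illuminant),
                numeric(length(s)))
  if (length(s) == 1) out <- matrix(out, nrow = 1)
  rownames(out) <- labels(s)
  colnames(out) <- vapply(ctx$receptors, `[[`, character(1), "name")
  out
}

#' von Kries chromatic adaptation
#'
#' Normalizes each receptor's catch by its catch for the adaptation
#' background, modelling receptor adaptation to illumination and background:
#' the background itself maps to relative catch 1 in every receptor, and any
#' rescaling of the illuminant cancels exactly.
#'
#' @param Q quantum catch (scalar, vector or matrix, receptors in columns).
#' @param Q_bg background catch for the same receptor(s); must be `> 0`.
#' @return relative catch `Q / Q_bg`.
#' @export
adapt_von_kries <- function(Q, Q_bg) {
  if (any(Q_bg <= 0)) stop("degenerate background: catch must be > 0", call. = FALSE)
  if (is.matrix(Q)) sweep(Q, 2, Q_bg, `/`) else Q / Q_bg
}

#' Hyperbolic phototransduction
#'
#' Maps a von Kries relative catch to a receptor excitation,
#' `E = q / (q + 1)`: monotone, bounded in `[0, 1)`, with the
#' background-adapted state at exactly 0.5.
#'
#' @param q relative quantum catch, `>= 0`.
#' @return excitation value(s).
#' @export
excite_hyperbolic <- function(q) {
  if (any(q < 0)) stop("relative catch must be non-negative", call. = FALSE)
  q / (q + 1)
}

#' Colour hexagon locus
#'
#' Projects the three receptor excitations of the trichromatic bee visual
#' system into the colour-hexagon plane: `x = sqrt(3)/2 * (E_g - E_uv)`,
#' `y = E_b - (E_uv + E_g)/2`. The adapted background (all excitations 0.5)
#' maps to the achromatic centre (0, 0). Hue sectors are the six 60-degree
#' sextants centred on the receptor axes (blue at 90 degrees, green at -30,
#' UV at 210), labelled uv, uv_blue, blue, blue_green, green, uv_green;
#' boundary angles are assigned counter-clockwise and loci within 1e-9 EU of
#' the centre are labelled "achromatic".
#'
#' @param e_uv,e_b,e_g excitations in `[0, 1)` (vectors accepted).
#' @return data.frame with columns `x`, `y`, `sector`.
#' @export
hexagon_locus <- function(e_uv, e_b, e_g) {
  stopifnot(all(e_uv >= 0 & e_uv < 1), all(e_b >= 0 & e_b < 1),
            all(e_g >= 0 & e_g < 1))
  x <- sqrt(3) / 2 * (e_g - e_uv)
  y <- e_b - (e_uv + e_g) / 2
  data.frame(x = x, y = y, sector = hexagon_sector(x, y))
}

hexagon_sector <- function(x, y) {
  r <- sqrt(x^2 + y^2)
  theta <- (atan2(y, x) * 180 / pi) %% 360
  idx <- pmin(floor(theta / 60) + 1L, 6L)
  out <- hexagon_sectors[idx]
  out[r < 1e-9] <- "achromatic"
  out
}

#' Fly colour-space locus
#'
#' The tetravariant fly colour space: von-Kries-adapted catches of the four
#' receptor classes are normalized to sum to one, and the opponent
#' coordinates are the direct differences of the pale and yellow channels,
#' `x = R7p - R8p`, `y = R7y - R8y` (each axis bounded in `[-1, 1]`). The
#' background maps to (0, 0). Quadrant colour categories come from the sign
#' pair of (x, y) through `quadrant_map`.
#'
#' @param q7p,q7y,q8p,q8y von-Kries-adapted relative catches (vectors
#'   accepted), `>= 0`.
#' @param quadrant_map sign-pair mapping; see [fly_quadrants_default].
#' @return data.frame with columns `x`, `y`, `sector`.
#' @export
fly_locus <- function(q7p, q7y, q8p, q8y,
                      quadrant_map = fly_quadrants_default) {
  stopifnot(all(q7p >= 0), all(q7y >= 0), all(q8p >= 0), all(q8y >= 0))
  tot <- q7p + q7y + q8p + q8y
  if (any(tot <= 0)) stop("all catches are zero; locus undefined", call. = FALSE)
  x <- (q7p - q8p) / tot
  y <- (q7y - q8y) / tot
  key <- paste0(ifelse(x >= 0, "+", "-"), ifelse(y >= 0, "+", "-"))
  sector <- unname(quadrant_map[key])
  sector[sqrt(x^2 + y^2) < 1e-9] <- "achromatic"
  data.frame(x = x, y = y, sector = sector)
}

#' Chromatic contrast
#'
#' Euclidean distance (EU) between a colour locus and the achromatic centre
#' of its colour space.
#'
#' @param x,y locus coordinates, or a data.frame with `x`,`y` as first arg.
#' @return non-negative distance in EU.
#' @export
chromatic_contrast <- function(x, y = NULL) {
  if (is.data.frame(x)) { y <- x$y; x <- x$x }
  sqrt(x^2 + y^2)
}

#' Achromatic (green-receptor) contrast
#'
#' The modulation of the green receptor against the background: the absolute
#' deviation of the green-receptor excitation from 0.5, the
#' background-adapted value. Defined for the bee model only.
#'
#' @param e_g green-receptor excitation in `[0, 1)`.
#' @return contrast in `[0, 0.5]`.
#' @export
achromatic_contrast <- function(e_g) {
  stopifnot(all(e_g >= 0 & e_g < 1))
  abs(e_g - 0.5)
}

#' Discriminability flag
#'
#' Whether a chromatic contrast reaches the discriminability threshold of
#' the model. The comparison is inclusive: a contrast exactly at the
#' threshold counts as discriminable.
#'
#' @param chromatic chromatic contrast (EU).
#' @param model `"hexagon"` or `"fly"`, or a `viewing_context`.
#' @param threshold override threshold (EU).
#' @return logical vector.
#' @export
flag_discriminable <- function(chromatic, model = c("hexagon", "fly"),
                               threshold = NULL) {
  if (inherits(model, "viewing_context")) {
    threshold <- threshold %||% model$threshold
  } else {
    model <- match.arg(model)
    threshold <- threshold %||% unname(default_thresholds[model])
  }
  chromatic >= threshold
}

#' Colour loci and contrasts for a spectrum set
#'
#' The main entry point of the vision module: maps every spectrum in the set
#' to its colour locus under the given viewing context and returns one row
#' per spectrum with coordinates, hue sector/quadrant, chromatic contrast,
#' achromatic contrast (bee model only, otherwise `NA`) and the
#' discriminability flag.
#'
#' @param ss a `spec_set`.
#' @param ctx a [viewing_context()].
#' @return data.frame with columns `label`, `group`, `model`, `x`, `y`,
#'   `sector`, `chromatic_EU`, `achromatic_EU`, `above_threshold`.
#' @export
colour_loci <- function(ss, ctx = viewing_context()) {
  stopifnot(inherits(ss, "spec_set"), inherits(ctx, "viewing_context"))
  Q <- receptor_catches(ss, ctx)
  q <- adapt_von_kries(Q, ctx$bg_catch)
  if (ctx$model == "hexagon") {
    E <- excite_hyperbolic(q)
    loc <- hexagon_locus(E[, 1], E[, 2], E[, 3])
    achro <- achromatic_contrast(E[, 3])
  } else {
    loc <- fly_locus(q[, 1], q[, 2], q[, 3], q[, 4],
                     quadrant_map = ctx$quadrant_map)
    achro <- rep(NA_real_, nrow(loc))
  }
  chrom <- chromatic_contrast(loc)
  data.frame(
    label = labels(ss),
    group = if (!is.null(ss$groups)) unname(ss$groups) else NA_character_,
    model = ctx$model,
    x = loc$x, y = loc$y, sector = loc$sector,
    chromatic_EU = chrom, achromatic_EU = achro,
    above_threshold = flag_discriminable(chrom, ctx),
    row.names = NULL)
}
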