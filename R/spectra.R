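#' Reflectance spectrum set
#'
#' The container every other module consumes: a set of reflectance spectra
#' sharing one wavelength grid. Reflectance is stored on the percent scale
#' (0--100), the convention of FReD-style exports.
#'
#' @param wl numeric wavelength grid (nm), strictly increasing.
#' @param refl numeric matrix of reflectance values (percent), one column per
#'   sample, `length(wl)` rows. A plain vector is taken as a single sample.
#' @param labels sample identifiers; defaults to the column names of `refl`.
#' @param groups optional named character vector mapping labels to colour
#'   classes (e.g. `"green"`, `"green_yellow"`).
#' @param n_aggregated integer count of raw samples each column averages
#'   (defaults to 1 per column).
#' @param sd optional matrix of per-wavelength standard deviations matching
#'   `refl` (present after [aggregate_spectra()]).
#' @return an object of class `spec_set`.
#' @seealso [read_spectra()], [aggregate_spectra()], [smooth_spectra()]
#' @export
spec_set <- function(wl, refl, labels = NULL, groups = NULL,
                     n_aggregated = NULL, sd = NULL) {
  if (is.vector(refl)) refl <- matrix(refl, ncol = 1)
  refl <- as.matrix(refl)
  if (!is.numeric(wl) || any(diff(wl) <= 0)) {
    stop("wavelengths must be numeric and strictly increasing", call. = FALSE)
  }
  if (nrow(refl) != length(wl)) {
    stop("reflectance length does not match the wavelength grid", call. = FALSE)
  }
  if (!all(is.finite(refl))) {
    stop("reflectance values must all be finite", call. = FALSE)
  }
  if (is.null(labels)) labels <- colnames(refl)
  if (is.null(labels)) labels <- paste0("s", seq_len(ncol(refl)))
  if (anyDuplicated(labels)) stop("sample labels must be unique", call. = FALSE)
  dimnames(refl) <- list(NULL, labels)
  if (!is.null(groups)) {
    if (is.null(names(groups))) {
      if (length(groups) != length(labels)) {
        stop("groups must be named by label or one per sample", call. = FALSE)
      }
      names(groups) <- labels
    }
    groups <- groups[labels]
  }
  if (is.null(n_aggregated)) n_aggregated <- stats::setNames(rep(1L, ncol(refl)), labels)
  if (!is.null(sd)) {
    sd <- as.matrix(sd)
    stopifnot(all(dim(sd) == dim(refl)))
    colnames(sd) <- labels
  }
  structure(
    list(wl = as.numeric(wl), refl = refl, groups = groups,
         n_aggregated = n_aggregated, sd = sd),
    class = "spec_set"
  )
}

#' @export
print.spec_set <- function(x, ...) {
  cat(sprintf("<spec_set> %d spectra on %g-%g nm (%d points)\n",
              ncol(x$refl), min(x$wl), max(x$wl), length(x$wl)))
  if (!is.null(x$groups)) {
    tab <- table(x$groups)
    cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.spec_set <- function(x, ...) {
  data.frame(wavelength_nm = x$wl, x$refl, check.names = FALSE)
}

#' @export
length.spec_set <- function(x) ncol(x$refl)

#' @export
labels.spec_set <- function(object, ...) colnames(object$refl)

#' Subset a spectrum set by sample
#'
#' @param x a `spec_set`.
#' @param i label names or indices of the samples to keep.
#' @param ... unused.
#' @export
`[.spec_set` <- function(x, i, ...) {
  refl <- x$refl[, i, drop = FALSE]
  spec_set(x$wl, refl,
           groups = if (!is.null(x$groups)) x$groups[colnames(refl)],
           n_aggregated = x$n_aggregated[colnames(refl)],
           sd = if (!is.null(x$sd)) x$sd[, i, drop = FALSE])
}

#' Validate a spectrum set
#'
#' Checks the container invariants: shared grid, finite values, and (after
#' negative-value correction) non-negativity.
#'
#' @param ss a `spec_set`.
#' @param require_nonnegative require all reflectance values `>= 0`.
#' @return `ss`, invisibly; errors describe the violated invariant.
#' @export
validate_spectra <- function(ss, require_nonnegative = TRUE) {
  stopifnot(inherits(ss, "spec_set"))
  if (any(diff(ss$wl) <= 0)) stop("grid not strictly increasing", call. = FALSE)
  if (!all(is.finite(ss$refl))) stop("non-finite reflectance", call. = FALSE)
  if (require_nonnegative && any(ss$refl < 0)) {
    stop("negative reflectance; run fix_negative()", call. = FALSE)
  }
  invisible(ss)
}

# ---- reading / writing -----------------------------------------------------

detect_sep <- function(lines) {
  if (sum(grepl("\t", lines)) >= sum(grepl(",", lines))) "\t" else ","
}

check_numeric_cols <- function(df, cols, path) {
  for (cn in cols) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & v != "")
      stop(sprintf("non-numeric value in column '%s' of %s (row %d: '%s')",
                   cn, path, bad[1], v[bad[1]]), call. = FALSE)
    }
  }
  invisible(df)
}

#' Read reflectance spectra from delimited text
#'
#' Supports the two dialects common for floral reflectance data: *long*
#' (FReD-style, columns `wavelength_nm, reflectance[, label]`, one block per
#' sample) and *wide* (first column `wavelength_nm`, one column per sample).
#' The field separator (comma or tab) is auto-detected. Spectra are resampled
#' by linear interpolation onto `grid`; wavelengths outside the grid range are
#' discarded. Files on a 0--1 reflectance scale (maximum value at most 1.5)
#' are detected and rescaled to percent with a message.
#'
#' @param path path to a delimited text file with a header row.
#' @param dialect `"auto"` (default), `"long"` or `"wide"`.
#' @param grid target wavelength grid; see [wl_grid()].
#' @return a [spec_set()].
#' @export
read_spectra <- function(path, dialect = c("auto", "long", "wide"),
                         grid = wl_grid()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  head_lines <- readLines(path, n = 20)
  sep <- detect_sep(head_lines)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "#")
  nm <- tolower(names(df))
  if (dialect == "auto") {
    dialect <- if (any(grepl("^reflect", nm))) "long" else "wide"
  }
  if (dialect == "long") {
    wcol <- which(grepl("^(wavelength|wl|lambda)", nm))[1]
    rcol <- which(grepl("^reflect", nm))[1]
    if (is.na(wcol) || is.na(rcol)) {
      stop("long dialect needs wavelength and reflectance columns", call. = FALSE)
    }
    lcol <- which(grepl("^(label|sample|species|id)$", nm))[1]
    check_numeric_cols(df, names(df)[c(wcol, rcol)], path)
    lab <- if (is.na(lcol)) rep("sample_1", nrow(df)) else as.character(df[[lcol]])
    pieces <- split(df[c(wcol, rcol)], factor(lab, levels = unique(lab)))
    refl <- sapply(pieces, function(p) {
      resample_one(p[[1]], p[[2]], grid)
    })
    ss <- spec_set(grid, refl, labels = names(pieces))
  } else {
    check_numeric_cols(df, names(df), path)
    wl_in <- df[[1]]
    if (any(diff(wl_in) <= 0)) {
      stop("wavelength column must be strictly increasing", call. = FALSE)
    }
    refl <- sapply(names(df)[-1], function(cn) resample_one(wl_in, df[[cn]], grid))
    ss <- spec_set(grid, refl, labels = names(df)[-1])
  }
  if (max(ss$refl) <= 1.5) {
    message("reflectance appears to be on a 0-1 scale; rescaling to percent")
    ss$refl <- ss$refl * 100
  }
  ss
}

resample_one <- function(wl_in, y, grid) {
  keep <- wl_in >= min(grid) - 1e-9 & wl_in <= max(grid) + 1e-9
  wl_in <- wl_in[keep]; y <- y[keep]
  if (length(wl_in) < 2 || min(wl_in) > min(grid) + 1e-9 ||
      max(wl_in) < max(grid) - 1e-9) {
    stop(sprintf(
      "wavelength coverage (%.1f-%.1f nm) narrower than the grid (%g-%g nm); extrapolation refused",
      if (length(wl_in)) min(wl_in) else NA, if (length(wl_in)) max(wl_in) else NA,
      min(grid), max(grid)), call. = FALSE)
  }
  stats::approx(wl_in, y, xout = grid, method = "linear", rule = 1)$y
}

#' Resample a spectrum set onto a new grid
#'
#' Linear interpolation; resampling onto the grid the set already lives on is
#' the identity. Extrapolation beyond the covered range is refused.
#'
#' @param ss a `spec_set`.
#' @param grid target wavelength grid.
#' @return a `spec_set` on `grid`.
#' @export
resample_spectra <- function(ss, grid = wl_grid()) {
  stopifnot(inherits(ss, "spec_set"))
  if (length(ss$wl) == length(grid) && all(abs(ss$wl - grid) < 1e-9)) return(ss)
  refl <- apply(ss$refl, 2, function(y) resample_one(ss$wl, y, grid))
  spec_set(grid, refl, groups = ss$groups, n_aggregated = ss$n_aggregated)
}

#' Write spectra to wide delimited text
#'
#' Writes the wide dialect [read_spectra()] reads back. Aggregated sets (with
#' a per-wavelength standard deviation) gain `_mean`/`_sd` column suffixes.
#'
#' @param ss a `spec_set`.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(ss, path, sep = "\t") {
  stopifnot(inherits(ss, "spec_set"))
  if (is.null(ss$sd)) {
    df <- data.frame(wavelength_nm = ss$wl, ss$refl, check.names = FALSE)
  } else {
    m <- ss$refl; colnames(m) <- paste0(colnames(ss$refl), "_mean")
    s <- ss$sd;   colnames(s) <- paste0(colnames(ss$refl), "_sd")
    df <- data.frame(wavelength_nm = ss$wl, m, s, check.names = FALSE)
  }
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- processing ------------------------------------------------------------

#' Smooth reflectance spectra
#'
#' Local-regression smoothing of each spectrum along the wavelength axis.
#' The smoothness parameter is the span: the fraction of the grid inside the
#' local fitting window. The default smoother is locally weighted least
#' squares with tricube weights (`stats::loess`, degree 2), which returns
#' constant and linear spectra unchanged up to numerical precision; a plain
#' centred moving average is available via `method = "movavg"`.
#'
#' @param ss a `spec_set`.
#' @param span smoothness parameter in (0, 1]; default 0.20.
#' @param method `"loess"` (default) or `"movavg"`.
#' @return a smoothed `spec_set` on the same grid.
#' @export
smooth_spectra <- function(ss, span = 0.20, method = c("loess", "movavg")) {
  stopifnot(inherits(ss, "spec_set"))
  method <- match.arg(method)
  if (!is.numeric(span) || length(span) != 1 || span <= 0 || span > 1) {
    stop("span must be a single number in (0, 1]", call. = FALSE)
  }
  wl <- ss$wl
  refl <- if (method == "loess") {
    apply(ss$refl, 2, function(y) {
      fit <- stats::loess(y ~ wl, span = span, degree = 2,
                          family = "gaussian",
                          control = stats::loess.control(surface = "direct"))
      as.numeric(stats::predict(fit, newdata = data.frame(wl = wl)))
    })
  } else {
    k <- max(1L, round(span * length(wl) / 2))
    apply(ss$refl, 2, moving_mean, halfwidth = k)
  }
  spec_set(wl, refl, groups = ss$groups, n_aggregated = ss$n_aggregated)
}

# centred moving mean with truncated windows at the ends
moving_mean <- function(y, halfwidth) {
  n <- length(y)
  cs <- cumsum(c(0, y))
  lo <- pmax(1L, seq_len(n) - halfwidth)
  hi <- pmin(n, seq_len(n) + halfwidth)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Correct negative reflectance values
#'
#' Minor calibration deviations can push reflectance slightly below zero.
#' For each spectrum whose minimum is negative, the absolute value of the
#' minimum is added to every wavelength, so the minimum becomes exactly zero
#' and the rank order of values is preserved (the additive correction).
#' Spectra already non-negative are returned unchanged; the operation is
#' idempotent.
#'
#' @param ss a `spec_set`.
#' @return a corrected `spec_set`.
#' @export
fix_negative <- function(ss) {
  stopifnot(inherits(ss, "spec_set"))
  mins <- apply(ss$refl, 2, min)
  shift <- pmax(0, -mins)
  ss$refl <- sweep(ss$refl, 2, shift, `+`)
  ss
}

#' Aggregate spectra by label grouping
#'
#' Averages replicate spectra per group (typically all measurements of one
#' species): the aggregated reflectance is the per-wavelength mean, with the
#' per-wavelength sample standard deviation stored alongside and
#' `n_aggregated` recording how many spectra each group averaged. Groups of a
#' single spectrum get standard deviation 0.
#'
#' @param ss a `spec_set`.
#' @param by named character vector mapping sample labels to aggregation
#'   groups; defaults to the set's `groups`.
#' @return a `spec_set` with one spectrum per group and an `sd` component.
#' @export
aggregate_spectra <- function(ss, by = ss$groups) {
  stopifnot(inherits(ss, "spec_set"))
  if (is.null(by)) stop("no grouping supplied and the set has no groups", call. = FALSE)
  by <- by[colnames(ss$refl)]
  if (anyNA(by)) stop("every sample needs an aggregation group", call. = FALSE)
  grps <- unique(unname(by))
  refl <- sapply(grps, function(g) rowMeans(ss$refl[, by == g, drop = FALSE]))
  sdev <- sapply(grps, function(g) {
    m <- ss$refl[, by == g, drop = FALSE]
    if (ncol(m) == 1) rep(0, nrow(m)) else apply(m, 1, stats::sd)
  })
  n_agg <- stats::setNames(as.integer(table(factor(unname(by), levels = grps))), grps)
  spec_set(ss$wl, refl, labels = grps, n_aggregated = n_agg, sd = sdev)
}
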