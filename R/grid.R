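#' Wavelength grid
#'
#' Construct the common wavelength grid all spectra are resampled onto.
#' The default covers the insect-relevant UV--VIS range, 300--700 nm
#' inclusive at 1 nm resolution (401 points).
#'
#' @param start_nm,stop_nm grid limits in nm; `start_nm < stop_nm`.
#' @param step_nm grid increment in nm; must be positive and divide the range.
#' @return numeric vector of wavelengths (nm).
#' @examples
#' length(wl_grid())  # 401
#' @export
wl_grid <- function(start_nm = 300, stop_nm = 700, step_nm = 1) {
  if (!is.numeric(start_nm) || !is.numeric(stop_nm) || !is.numeric(step_nm) ||
      length(start_nm) != 1 || length(stop_nm) != 1 || length(step_nm) != 1) {
    stop("grid limits and step must be single numbers", call. = FALSE)
  }
  if (start_nm >= stop_nm) stop("start_nm must be < stop_nm", call. = FALSE)
  if (step_nm <= 0) stop("step_nm must be > 0", call. = FALSE)
  wl <- seq(start_nm, stop_nm, by = step_nm)
  if (abs(wl[length(wl)] - stop_nm) > 1e-9) {
    stop("step_nm must divide the grid range exactly", call. = FALSE)
  }
  wl
}

grid_step <- function(wl) {
  d <- diff(wl)
  if (max(d) - min(d) > 1e-9) stop("grid is not equally spaced", call. = FALSE)
  d[1]
}
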