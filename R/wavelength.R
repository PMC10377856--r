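#' Wavelength sampling grid for spectral cubes
#'
#' The visible-range grid on which every reflectance spectrum in the package
#' lives. The default covers 380-780 nm in 1 nm steps, i.e. 401 bands.
#'
#' @param start First wavelength in nm.
#' @param stop Last wavelength in nm.
#' @param step Band spacing in nm; must divide `stop - start`.
#' @return An object of class `wavelength_grid`: a list with `start`, `stop`,
#'   `step`, `count` and the sampled wavelengths `nm`.
#' @examples
#' g <- wavelength_grid()
#' g$count # 401
#' @export
wavelength_grid <- function(start = 380, stop = 780, step = 1) {
  stopifnot(is.numeric(start), is.numeric(stop), is.numeric(step))
  if (step <= 0) stop("`step` must be positive")
  if (stop <= start) stop("`stop` must exceed `start`")
  n_steps <- (stop - start) / step
  if (abs(n_steps - round(n_steps)) > 1e-9) {
    stop("`step` must divide the span `stop - start` exactly")
  }
  nm <- seq(start, stop, by = step)
  structure(
    list(start = start, stop = stop, step = step,
         count = length(nm), nm = nm),
    class = "wavelength_grid"
  )
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %g-%g nm, step %g nm (%d bands)\n",
              x$start, x$stop, x$step, x$count))
  invisible(x)
}

grids_identical <- function(a, b) {
  isTRUE(all.equal(a$nm, b$nm, tolerance = 1e-9))
}

#' Index of a wavelength window on a grid
#'
#' @param grid A [wavelength_grid()].
#' @param window Numeric length-2 `c(lo, hi)` in nm, inclusive.
#' @return Integer indices of the bands inside the window.
#' @keywords internal
window_index <- function(grid, window) {
  stopifnot(length(window) == 2)
  if (window[1] >= window[2]) stop("window must satisfy lo < hi")
  if (window[1] < grid$start || window[2] > grid$stop) {
    stop(sprintf("window [%g, %g] nm lies outside the grid %g-%g nm",
                 window[1], window[2], grid$start, grid$stop))
  }
  which(grid$nm >= window[1] & grid$nm <= window[2])
}
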