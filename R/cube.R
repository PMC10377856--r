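# Reflectance cube container: a plain H x W x B numeric array carrying its
# wavelength grid as an attribute. Kept deliberately light-weight — cubes are
# large and short-lived, so no copy-heavy class machinery.

new_reflectance_cube <- function(a, grid) {
  stopifnot(length(dim(a)) == 3, dim(a)[3] == grid$count)
  structure(a, class = "reflectance_cube", grid = grid)
}

#' Wavelength grid of a reflectance cube
#' @param cube A `reflectance_cube`.
#' @return The [wavelength_grid()] the cube is sampled on.
#' @export
cube_grid <- function(cube) {
  g <- attr(cube, "grid")
  if (is.null(g)) stop("object carries no wavelength grid attribute")
  g
}

#' @export
print.reflectance_cube <- function(x, ...) {
  d <- dim(x)
  g <- attr(x, "grid")
  cat(sprintf("<reflectance_cube> %d x %d pixels, %d bands (%g-%g nm)\n",
              d[1], d[2], d[3], g$start, g$stop))
  invisible(x)
}

# flatten to (H*W) x B spectra matrix
cube_spectra <- function(cube) {
  d <- dim(cube)
  matrix(cube, nrow = d[1] * d[2], ncol = d[3])
}

#' Root-mean-square error between two reflectance cubes
#'
#' RMSE over all pixels and bands, in reflectance units.
#'
#' @param estimate,truth Arrays of identical dimensions.
#' @return A scalar.
#' @examples
#' a <- array(0.5, c(2, 2, 5)); b <- array(0.6, c(2, 2, 5))
#' reconstruction_rmse(a, b) # 0.1
#' @export
reconstruction_rmse <- function(estimate, truth) {
  if (!identical(dim(estimate), dim(truth))) {
    stop("cube shapes differ: ",
         paste(dim(estimate), collapse = "x"), " vs ",
         paste(dim(truth), collapse = "x"))
  }
  sqrt(mean((as.numeric(estimate) - as.numeric(truth))^2))
}
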