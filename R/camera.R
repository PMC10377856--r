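# Colorimetric forward model: spectra -> RGB.
#
# The observer weights use the published piecewise-Gaussian analytic fit to
# the CIE 1931 2-degree color-matching functions (sum of asymmetric Gaussian
# lobes); the illuminant is a normalized Planckian radiator at ~6500 K, a
# standard stand-in for average daylight. Both are evaluated directly on the
# requested grid, so the forward model is fully reproducible offline.

# asymmetric Gaussian lobe: different inverse-widths left/right of the mode
.lobe <- function(x, mu, inv_s1, inv_s2) {
  s <- ifelse(x < mu, inv_s1, inv_s2)
  exp(-0.5 * ((x - mu) * s)^2)
}

#' Color-matching weights on a wavelength grid
#'
#' Analytic piecewise-Gaussian approximation to the 2-degree standard
#' observer, evaluated at the grid wavelengths.
#'
#' @param grid A [wavelength_grid()].
#' @return A 3 x `grid$count` matrix with rows `x`, `y`, `z`.
#' @keywords internal
cie_cmf <- function(grid) {
  wl <- grid$nm
  if (min(wl) < 360 || max(wl) > 830) {
    bad <- wl[wl < 360 | wl > 830]
    stop(sprintf(
      "observer weights are tabulated for 360-830 nm; offending wavelengths: %s",
      paste(utils::head(bad, 5), collapse = ", ")))
  }
  xb <- 0.362 * .lobe(wl, 442.0, 0.0624, 0.0374) +
        1.056 * .lobe(wl, 599.8, 0.0264, 0.0323) -
        0.065 * .lobe(wl, 501.1, 0.0490, 0.0382)
  yb <- 0.821 * .lobe(wl, 568.8, 0.0213, 0.0247) +
        0.286 * .lobe(wl, 530.9, 0.0613, 0.0322)
  zb <- 1.217 * .lobe(wl, 437.0, 0.0845, 0.0278) +
        0.681 * .lobe(wl, 459.0, 0.0385, 0.0725)
  m <- rbind(x = xb, y = yb, z = zb)
  colnames(m) <- as.character(wl)
  m
}

#' Daylight-like illuminant spectral power distribution
#'
#' Planck's law at 6504 K, normalized to 1 at 560 nm.
#'
#' @param grid A [wavelength_grid()].
#' @return Numeric vector of relative spectral power per band.
#' @keywords internal
daylight_spd <- function(grid, temp_k = 6504) {
  planck <- function(lambda_nm) {
    l <- lambda_nm * 1e-9
    h <- 6.62607015e-34; c <- 2.99792458e8; kb <- 1.380649e-23
    (2 * h * c^2 / l^5) / (exp(h * c / (l * kb * temp_k)) - 1)
  }
  planck(grid$nm) / planck(560)
}

# sRGB colorimetry constants (IEC 61966-2-1)
.M_XYZ2RGB <- matrix(c( 3.2406, -1.5372, -0.4986,
                       -0.9689,  1.8758,  0.0415,
                        0.0557, -0.2040,  1.0570), 3, 3, byrow = TRUE)
.M_RGB2XYZ <- matrix(c(0.4124, 0.3576, 0.1805,
                       0.2126, 0.7152, 0.0722,
                       0.0193, 0.1192, 0.9505), 3, 3, byrow = TRUE)

#' sRGB transfer (gamma) encoding and decoding
#'
#' @param x Linear values (encode) or encoded values (decode), any shape.
#' @return Same shape as `x`.
#' @keywords internal
srgb_encode <- function(x) {
  ifelse(x <= 0.0031308, 12.92 * x, 1.055 * pmax(x, 0)^(1 / 2.4) - 0.055)
}

#' @rdname srgb_encode
#' @keywords internal
srgb_decode <- function(x) {
  ifelse(x <= 0.04045, x / 12.92, ((x + 0.055) / 1.055)^2.4)
}

# round half away from zero (kept explicit so 8-bit round trips are bit-stable)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Build the spectral camera forward model
#'
#' Bundles the wavelength grid, a daylight-like illuminant, observer
#' color-matching weights, the sRGB transfer function, and the white point
#' (the rendering of a unit reflectance) into a camera model used both to
#' synthesize images and to define calibration reference values.
#'
#' @param grid A [wavelength_grid()]; defaults to 380-780 nm in 1 nm steps.
#' @return An object of class `camera_model`.
#' @examples
#' cam <- make_camera_model()
#' dim(cam$cmf) # 3 x 401
#' @export
make_camera_model <- function(grid = wavelength_grid()) {
  stopifnot(inherits(grid, "wavelength_grid"))
  cmf <- cie_cmf(grid)
  illum <- daylight_spd(grid)
  # normalization so that unit reflectance has Y = 1
  k_norm <- sum(illum * cmf["y", ]) * grid$step
  white_xyz <- as.numeric(cmf %*% illum) * grid$step / k_norm
  if (any(white_xyz <= 0)) stop("degenerate white point")
  structure(
    list(grid = grid, illuminant = illum, cmf = cmf,
         k_norm = k_norm, white_point = white_xyz,
         gamma_transfer = "srgb"),
    class = "camera_model"
  )
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model> grid %g-%g nm (%d bands), white XYZ = (%.4f, %.4f, %.4f)\n",
              x$grid$start, x$grid$stop, x$grid$count,
              x$white_point[1], x$white_point[2], x$white_point[3]))
  invisible(x)
}

# Integrate spectra against illuminant x cmf. `spectra` is N x B; returns N x 3
# (XYZ, normalized so unit reflectance gives Y = 1 for the full-grid camera).
camera_xyz <- function(spectra, camera, band_idx = NULL, k_norm = NULL) {
  stopifnot(is.matrix(spectra))
  idx <- if (is.null(band_idx)) seq_len(camera$grid$count) else band_idx
  if (ncol(spectra) != length(idx)) stop("spectra bands do not match index")
  w <- t(camera$cmf[, idx, drop = FALSE] *
           rep(camera$illuminant[idx], each = 3)) * camera$grid$step
  k <- if (is.null(k_norm)) camera$k_norm else k_norm
  (spectra %*% w) / k
}

# XYZ (N x 3) -> white-balanced encoded sRGB in [0,1]. White balancing is a
# von Kries diagonal scaling in XYZ that maps `white_xyz` onto the sRGB
# white, so unit reflectance renders channel-equal for any illuminant or
# band window (band-limited whites have no nonnegative RGB representation,
# which rules out balancing in RGB space).
.WHITE_SRGB_XYZ <- as.numeric(.M_RGB2XYZ %*% c(1, 1, 1))

xyz_to_encoded_rgb <- function(xyz, white_xyz) {
  scaled <- sweep(xyz, 2, .WHITE_SRGB_XYZ / white_xyz, "*")
  rgb_lin <- scaled %*% t(.M_XYZ2RGB)
  srgb_encode(pmin(pmax(rgb_lin, 0), 1))
}

#' Render a reflectance scene or cube to an 8-bit RGB fundus image
#'
#' Integrates each pixel's reflectance against the camera's illuminant and
#' color-matching weights, white-balances against the camera white point
#' (so a unit reflectance renders channel-equal), gamma-encodes and
#' quantizes to 8 bits (round half away from zero).
#'
#' @param scene A `reflectance_scene` from [generate_scene()], or a bare
#'   `H x W x B` reflectance array with a `grid` attribute.
#' @param camera A [make_camera_model()] whose grid matches the scene.
#' @return A `fundus_image`: integer `H x W x 3` array in 0..255 with the
#'   scene's landmarks, label and covariates attached as attributes.
#' @export
render <- function(scene, camera) {
  cube <- if (inherits(scene, "reflectance_scene")) scene$cube else scene
  grid <- cube_grid(cube)
  if (!grids_identical(grid, camera$grid)) {
    stop("scene and camera wavelength grids differ")
  }
  d <- dim(cube)
  spectra <- matrix(cube, nrow = d[1] * d[2], ncol = d[3])
  xyz <- camera_xyz(spectra, camera)
  enc <- xyz_to_encoded_rgb(xyz, camera$white_point)
  img <- array(as.integer(round_half_away(enc * 255)), dim = c(d[1], d[2], 3))
  new_fundus_image(img,
                   landmarks = if (inherits(scene, "reflectance_scene")) scene$landmarks else NULL,
                   label = if (inherits(scene, "reflectance_scene")) scene$label else NULL,
                   covariates = if (inherits(scene, "reflectance_scene")) scene$covariates else NULL)
}

new_fundus_image <- function(pixels, landmarks = NULL, label = NULL,
                             covariates = NULL, image_id = NULL) {
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 3)
  structure(pixels, class = "fundus_image", landmarks = landmarks,
            label = label, covariates = covariates, image_id = image_id)
}

#' @export
print.fundus_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<fundus_image> %d x %d x 3, 8-bit%s\n", d[1], d[2],
              if (!is.null(attr(x, "label"))) paste0(", label = ", attr(x, "label")) else ""))
  invisible(x)
}

#' Convert 8-bit sRGB values to standard tristimulus (XYZ)
#'
#' Linearizes the sRGB transfer function and applies the fixed sRGB-to-XYZ
#' matrix. This is the front end of the spectral reconstruction: device
#' colors are first expressed in a device-independent tristimulus space,
#' which the calibration's polynomial color correction then maps onto the
#' camera-model reference tristimulus.
#'
#' @param rgb Numeric vector of 3, or an `N x 3` matrix, of 8-bit values in
#'   0..255.
#' @return A length-3 vector (or `N x 3` matrix) of XYZ values; (0,0,0) maps
#'   to (0,0,0) and (255,255,255) to the sRGB white point.
#' @export
srgb_to_tristimulus <- function(rgb) {
  vec_in <- is.null(dim(rgb))
  m <- if (vec_in) matrix(rgb, ncol = 3) else as.matrix(rgb)
  if (ncol(m) != 3) stop("rgb must have 3 channels")
  if (any(m < 0 | m > 255)) stop("8-bit RGB values must lie in [0, 255]")
  xyz <- srgb_decode(m / 255) %*% t(.M_RGB2XYZ)
  if (vec_in) as.numeric(xyz) else xyz
}
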