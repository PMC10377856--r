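# RGB -> 401-band spectral reconstruction.
#
# Two-stage scheme: (1) a degree-3 polynomial color correction maps device
# tristimulus (sRGB-decoded XYZ) onto reference tristimulus computed from the
# calibration patch spectra under the camera model; (2) patch spectra are
# decomposed into a mean plus k principal spectral components, and a
# ridge-regularized polynomial regression maps corrected tristimulus onto the
# component scores. Per-pixel reconstruction is then
#   spectrum(rgb) = mu + basis %*% scores(rgb), clipped to [0, 1].
# The reconstruction is a function of color alone (two pixels with the same
# RGB always receive the same spectrum).

# exponent table for all monomials of (x, y, z) with total degree <= 3,
# ordered by total degree, then lexicographically by decreasing exponent of
# x, then y. Fixed order; length 20.
.POLY_EXPONENTS <- local({
  ex <- NULL
  for (d in 0:3) for (i in d:0) for (j in (d - i):0) {
    ex <- rbind(ex, c(i, j, d - i - j))
  }
  ex
})

#' Polynomial feature expansion of a tristimulus vector
#'
#' All 20 monomials of `(X, Y, Z)` of total degree <= 3, including the
#' constant term. Term order: by total degree, then lexicographically by
#' decreasing exponent of X, then of Y (so: 1, X, Y, Z, X^2, XY, XZ, Y^2,
#' YZ, Z^2, X^3, ...).
#'
#' @param t Length-3 numeric vector, or an `N x 3` matrix.
#' @return Length-20 vector (or `N x 20` matrix) of features.
#' @examples
#' poly_features(c(0, 0, 0)) # 1 followed by 19 zeros
#' @export
poly_features <- function(t) {
  vec_in <- is.null(dim(t))
  m <- if (vec_in) matrix(t, ncol = 3) else as.matrix(t)
  if (ncol(m) != 3) stop("tristimulus input must have 3 components")
  f <- apply(.POLY_EXPONENTS, 1, function(e)
    m[, 1]^e[1] * m[, 2]^e[2] * m[, 3]^e[3])
  f <- matrix(f, nrow = nrow(m))
  if (vec_in) as.numeric(f) else f
}

#' Fit the RGB-to-spectrum calibration from a color checker
#'
#' @param checker A [generate_checker()] calibration set (or any list with
#'   `patch_spectra`, `patch_rgb`, `grid`).
#' @param camera The [make_camera_model()] defining reference tristimulus.
#' @param k Number of principal spectral components retained (default 12).
#' @param lambda Ridge penalty for the score regression (default 1e-3).
#' @return A `calibration_model` with the color-correction matrix, spectral
#'   mean and basis, score map, and a `fit_report` containing `train_rmse`
#'   and per-patch RMSEs.
#' @export
fit_calibration <- function(checker, camera, k = 12, lambda = 1e-3) {
  spectra <- checker$patch_spectra
  P <- nrow(spectra)
  n_feat <- nrow(.POLY_EXPONENTS)
  if (P < n_feat) {
    stop(sprintf("need at least %d training patches for the degree-3 expansion, got %d; add patches",
                 n_feat, P))
  }
  if (k > P) stop("k cannot exceed the number of training patches")
  if (!grids_identical(checker$grid, camera$grid)) {
    stop("checker and camera wavelength grids differ")
  }

  # stage 1: polynomial color correction, device XYZ -> reference XYZ
  dev_xyz <- srgb_to_tristimulus(checker$patch_rgb)
  ref_xyz <- camera_xyz(spectra, camera)
  Phi <- poly_features(dev_xyz)
  cc <- qr.solve(Phi, ref_xyz)                       # 20 x 3
  corr_xyz <- Phi %*% cc

  # stage 2: principal spectral components and ridge score regression
  mu <- colMeans(spectra)
  sv <- svd(sweep(spectra, 2, mu), nu = 0, nv = k)
  basis <- sv$v                                      # B x k, orthonormal columns
  scores <- sweep(spectra, 2, mu) %*% basis          # P x k
  # ridge solution via SVD of the feature matrix (stable down to lambda ~ 0)
  Phi2 <- poly_features(corr_xyz)
  sv2 <- svd(Phi2)
  shrink <- sv2$d / (sv2$d^2 + lambda)
  score_map <- sv2$v %*% (shrink * (t(sv2$u) %*% scores))   # 20 x k

  recon <- pmin(pmax(sweep((Phi2 %*% score_map) %*% t(basis), 2, mu, "+"), 0), 1)
  per_patch <- sqrt(rowMeans((recon - spectra)^2))
  structure(
    list(color_correction = cc, basis_mean = mu, basis = basis,
         score_map = score_map, k = k, lambda = lambda,
         grid = checker$grid,
         fit_report = list(train_rmse = sqrt(mean((recon - spectra)^2)),
                           per_patch_rmse = per_patch)),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> k = %d components, train RMSE = %.4g\n",
              x$k, x$fit_report$train_rmse))
  invisible(x)
}

# reconstruct spectra for an N x 3 matrix of 8-bit RGB rows
reconstruct_spectra <- function(rgb, model) {
  Phi2 <- poly_features(poly_features(srgb_to_tristimulus(rgb)) %*%
                          model$color_correction)
  pmin(pmax(sweep((Phi2 %*% model$score_map) %*% t(model$basis),
                  2, model$basis_mean, "+"), 0), 1)
}

#' Convert an 8-bit RGB image to a reflectance cube
#'
#' Applies the calibrated reconstruction per pixel. Distinct colors are
#' reconstructed once and cached, which changes nothing in the result but
#' makes large images cheap (an 8-bit image has at most 256^3 distinct
#' colors, and a fundus image far fewer).
#'
#' @param image A `fundus_image` (or plain integer `H x W x 3` array, 0..255).
#' @param model A fitted [fit_calibration()] model.
#' @return A `reflectance_cube` of shape `H x W x B` on the model's grid.
#' @export
rgb_to_cube <- function(image, model) {
  if (!inherits(model, "calibration_model")) {
    stop("`model` must be a fitted calibration_model (see fit_calibration)")
  }
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3) stop("image must be H x W x 3")
  px <- matrix(as.integer(image), ncol = 3)
  key <- px[, 1] * 65536L + px[, 2] * 256L + px[, 3]
  uk <- unique(key)
  uidx <- match(uk, key)
  spec_u <- reconstruct_spectra(px[uidx, , drop = FALSE], model)
  spec <- spec_u[match(key, uk), , drop = FALSE]
  new_reflectance_cube(array(spec, c(d[1], d[2], model$grid$count)),
                       model$grid)
}
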