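# Calibration target: a synthetic color-checker whose patch spectra are
# smooth and whose RGB values are exactly the camera-model rendering of those
# spectra. Used to fit the RGB -> spectrum reconstruction.
#
# The patches sample the reflectance manifold of the scenes being imaged
# (region-signature mixtures, brightness scalings, age tilts, and window
# perturbations with smooth shoulders): a calibration target is only useful
# if it spans the spectra the camera will actually see.

# render a spectra matrix (N x B) to 8-bit RGB through the camera code path
render_spectra <- function(spectra, camera) {
  xyz <- camera_xyz(spectra, camera)
  enc <- xyz_to_encoded_rgb(xyz, camera$white_point)
  matrix(as.integer(round_half_away(enc * 255)), ncol = 3,
         dimnames = list(NULL, c("R", "G", "B")))
}

# smooth-shouldered band multiplier, ~1 outside [lo, hi], 1 + d inside
smooth_window_gain <- function(nm, d, lo = 500, hi = 600, shoulder = 6) {
  1 + d * stats::plogis((nm - lo) / shoulder) * stats::plogis((hi - nm) / shoulder)
}

# additive age-like tilt with a smooth pivot at 530 nm (+a short, -a long)
smooth_tilt <- function(nm, a, pivot = 530, width = 8) {
  a * (1 - 2 * stats::plogis((nm - pivot) / width))
}

# 24 fixed patches: the four region signatures at three brightness levels,
# their pairwise midpoints, two age tilts, and four window perturbations.
canonical_patches <- function(grid) {
  S <- region_spectra(grid)
  p <- NULL
  for (b in c(0.7, 1.0, 1.25)) p <- rbind(p, S * b)
  pairs <- utils::combn(4, 2)
  mids <- t(apply(pairs, 2, function(ij) (S[ij[1], ] + S[ij[2], ]) / 2))
  tilts <- t(sapply(c(-0.012, 0.012), function(a)
    S["background", ] + smooth_tilt(grid$nm, a)))
  wins <- t(sapply(c(-0.08, -0.04, 0.04, 0.08), function(d)
    S["background", ] * smooth_window_gain(grid$nm, d)))
  out <- pmin(pmax(rbind(p, mids, tilts, wins), 0), 1)
  stopifnot(nrow(out) == 24)
  rownames(out) <- NULL
  out
}

# random in-family patches: region mixtures x brightness x tilt x window gain
random_patches <- function(grid, n, seed) {
  S <- region_spectra(grid)
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  out <- t(sapply(seq_len(n), function(i) {
    w <- stats::rgamma(4, 1); w <- w / sum(w)
    s <- as.numeric(w %*% S)
    s <- s + smooth_tilt(grid$nm, stats::rnorm(1, 0, 0.01))
    if (stats::runif(1) < 0.5) {
      s <- s * smooth_window_gain(grid$nm, stats::runif(1, -0.08, 0.08))
    }
    if (stats::runif(1) < 0.5) {
      s <- s * (1 + stats::rnorm(1, 0, 0.2) * nuisance_shape(grid))
    }
    s <- s * stats::runif(1, 0.6, 1.3)
    pmin(pmax(s, 0), 1)
  }))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  out
}

#' Generate a synthetic color-checker calibration set
#'
#' 24 canonical fundus-domain patches (region signatures, brightness levels,
#' mixtures, age tilts, window perturbations) plus `n_extra` random smooth
#' in-family spectra, each rendered to 8-bit RGB through the camera forward
#' model.
#'
#' @param camera A [make_camera_model()].
#' @param n_extra Number of additional random patches (default 100).
#' @param seed Integer RNG seed for the random patches.
#' @return A `color_checker`: list with `patch_spectra` (`P x B`),
#'   `patch_rgb` (`P x 3`, 8-bit) and the grid.
#' @export
generate_checker <- function(camera, n_extra = 100, seed = 1) {
  stopifnot(n_extra >= 0)
  grid <- camera$grid
  spectra <- canonical_patches(grid)
  if (n_extra > 0) spectra <- rbind(spectra, random_patches(grid, n_extra, seed))
  structure(
    list(patch_spectra = spectra,
         patch_rgb = render_spectra(spectra, camera),
         grid = grid),
    class = "color_checker"
  )
}

#' @export
print.color_checker <- function(x, ...) {
  cat(sprintf("<color_checker> %d patches, %d bands\n",
              nrow(x$patch_spectra), ncol(x$patch_spectra)))
  invisible(x)
}

#' Maximum absolute second difference of patch spectra
#'
#' Smoothness diagnostic for a calibration set: the largest absolute second
#' difference (per nm^2) over all patches. Values below ~5e-3 per nm^2
#' indicate spectra free of sharp kinks at the grid scale.
#'
#' @param checker A [generate_checker()] result.
#' @return A scalar.
#' @export
checker_smoothness <- function(checker) {
  step <- checker$grid$step
  d2 <- t(apply(checker$patch_spectra, 1, function(s) diff(s, differences = 2)))
  max(abs(d2)) / step^2
}
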