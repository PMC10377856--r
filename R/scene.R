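# Synthetic fundus reflectance scenes.
#
# Each scene is a per-pixel reflectance cube composed from a small set of
# smooth spectral signatures (background fundus, vessel, fovea, optic disc)
# blended by spatial weight maps, plus:
#   * an age effect: additive tilt, positive below 530 nm and negative above,
#     proportional to (age - 60);
#   * the case signal: reflectance inside a configurable window (default
#     500-600 nm) multiplied by (1 + delta) for label "hcq";
#   * a per-scene smooth spectral confounder concentrated outside the window
#     (random amplitude), emulating acquisition/pigmentation variation;
#   * i.i.d. pixel noise.
# Diabetic-retinopathy stage has no spectral effect by design.

gaussian_band <- function(nm, mu, sigma) exp(-((nm - mu)^2) / (2 * sigma^2))

# Spectral shape of the per-scene confounder: two narrow bumps flanking the
# default 500-600 nm case window (negligible inside it), placed where the
# luminance weighting still has support, so broadband color channels are
# contaminated but the band-selected window is not.
nuisance_shape <- function(grid) {
  gaussian_band(grid$nm, 470, 18) + gaussian_band(grid$nm, 635, 18)
}

# Smooth spectral building blocks shared by the scene and checker generators.
spectral_basis <- function(grid) {
  nm <- grid$nm
  list(
    const   = rep(1, grid$count),
    lin     = (nm - grid$start) / (grid$stop - grid$start),
    decline = exp(-(nm - grid$start) / 270),          # melanin-like
    hb540   = gaussian_band(nm, 540, 15),             # oxyhemoglobin dips
    hb575   = gaussian_band(nm, 575, 15),
    blue460 = gaussian_band(nm, 460, 40)              # macular-pigment-like
  )
}

# region signatures: coefficient rows on (const, lin, decline, hb540, hb575, blue460)
.REGION_COEF <- rbind(
  background = c(0.30, 0.30, -0.18, -0.10, -0.08,  0.00),
  vessel     = c(0.16, 0.18, -0.10, -0.16, -0.13,  0.00),
  fovea      = c(0.24, 0.26, -0.20, -0.10, -0.08, -0.08),
  disc       = c(0.55, 0.25, -0.10, -0.04, -0.03,  0.00)
)

region_spectra <- function(grid) {
  b <- spectral_basis(grid)
  B <- cbind(b$const, b$lin, b$decline, b$hb540, b$hb575, b$blue460)
  s <- .REGION_COEF %*% t(B)          # 4 x B
  pmin(pmax(s, 0), 1)
}

#' Parameters for a synthetic reflectance scene
#'
#' The defaults define the study conditions every downstream stage is tested
#' against: a 500-600 nm case window, a 5% multiplicative case effect, an age
#' tilt pivoting at 530 nm, no diabetic-retinopathy effect, and mild pixel
#' noise.
#'
#' @param label `"normal"` or `"hcq"`.
#' @param age Subject age in years; drives the additive spectral tilt.
#' @param delta Multiplicative case effect inside `window` (label `"hcq"` only).
#' @param window Numeric `c(lo, hi)` nm where the case signal lives.
#' @param spatial_extent `"global"` (whole field) or `"fovea"` (case effect
#'   weighted by the foveal mask, for localization experiments).
#' @param noise_sd Standard deviation of i.i.d. pixel reflectance noise.
#' @param nuisance_sd Standard deviation of the per-scene amplitude of the
#'   smooth out-of-window spectral confounder (0 disables it).
#' @param size Image size `c(H, W)` in pixels.
#' @param age_slope Tilt per year of age above 60, in reflectance units.
#' @param fovea_center,disc_center Optional `(row, col)`; defaults are placed
#'   proportionally to `size`.
#' @param arcade_half_height Vertical distance in pixels from fovea to the
#'   temporal vascular arcades; defaults to 0.28 H.
#' @param covariates Optional named list merged into the scene covariates
#'   (e.g. `sex`, `hbp`, `glaucoma`, `amd`, `dr_stage`).
#' @param grid A [wavelength_grid()].
#' @return A list of validated parameters for [generate_scene()].
#' @export
scene_params <- function(label = c("normal", "hcq"), age = 75,
                         delta = 0.05, window = c(500, 600),
                         spatial_extent = c("global", "fovea"),
                         noise_sd = 0.005, nuisance_sd = 0,
                         size = c(512, 512), age_slope = 5e-4,
                         fovea_center = NULL, disc_center = NULL,
                         arcade_half_height = NULL,
                         covariates = list(), grid = wavelength_grid()) {
  label <- match.arg(label)
  spatial_extent <- match.arg(spatial_extent)
  stopifnot(length(size) == 2, all(size >= 16), age > 0, delta > -1,
            noise_sd >= 0, nuisance_sd >= 0)
  window_index(grid, window) # validates the window against the grid
  H <- size[1]; W <- size[2]
  if (is.null(fovea_center)) fovea_center <- c(0.50 * H, 0.60 * W)
  if (is.null(disc_center))  disc_center  <- c(0.46 * H, 0.18 * W)
  if (is.null(arcade_half_height)) arcade_half_height <- 0.28 * H
  list(label = label, age = age, delta = delta, window = window,
       spatial_extent = spatial_extent, noise_sd = noise_sd,
       nuisance_sd = nuisance_sd, size = size, age_slope = age_slope,
       fovea_center = fovea_center, disc_center = disc_center,
       arcade_half_height = arcade_half_height,
       covariates = covariates, grid = grid)
}

# spatial weight maps in [0,1]: fovea blob, disc disk, vessel arcs
scene_weight_maps <- function(p) {
  H <- p$size[1]; W <- p$size[2]
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  sig_f <- 0.055 * W
  w_fovea <- exp(-((rows - p$fovea_center[1])^2 + (cols - p$fovea_center[2])^2) /
                   (2 * sig_f^2))
  r_disc <- 0.065 * W
  d_disc <- sqrt((rows - p$disc_center[1])^2 + (cols - p$disc_center[2])^2)
  w_disc <- stats::plogis((r_disc - d_disc) / (0.01 * W + 0.5))
  # arcades: arcs leaving the disc, flattening at +-arcade_half_height
  frac <- pmin(pmax((cols - p$disc_center[2]) / (W - p$disc_center[2]), 0), 1)
  arc_off <- p$arcade_half_height * sqrt(frac)
  vw <- pmax(1.2, 0.005 * W)
  w_ves <- exp(-((rows - (p$fovea_center[1] - arc_off))^2) / (2 * vw^2)) +
           exp(-((rows - (p$fovea_center[1] + arc_off))^2) / (2 * vw^2))
  w_ves <- pmin(w_ves, 1) * (frac > 0.02)
  list(fovea = w_fovea, disc = w_disc, vessel = w_ves)
}

#' Generate a synthetic fundus reflectance scene
#'
#' Deterministic given `(params, seed)`: identical inputs reproduce the cube
#' bit for bit. All reflectance values are clipped to `[0, 1]`.
#'
#' @param params A [scene_params()] list.
#' @param seed Integer RNG seed.
#' @return A `reflectance_scene`: list with `cube` (`H x W x B`
#'   `reflectance_cube`), `landmarks`, `label`, `covariates` and `seed`.
#' @examples
#' sc <- generate_scene(scene_params(size = c(32, 32)), seed = 1)
#' range(sc$cube) # within [0, 1]
#' @export
generate_scene <- function(params, seed) {
  p <- params
  grid <- p$grid
  H <- p$size[1]; W <- p$size[2]; B <- grid$count
  maps <- scene_weight_maps(p)
  w_bg <- pmax(0, 1 - maps$fovea - maps$disc - maps$vessel)
  wsum <- w_bg + maps$fovea + maps$disc + maps$vessel
  Wmat <- cbind(as.numeric(w_bg), as.numeric(maps$vessel),
                as.numeric(maps$fovea), as.numeric(maps$disc)) / as.numeric(wsum)
  S <- region_spectra(grid)[c("background", "vessel", "fovea", "disc"), ]
  flat <- Wmat %*% S                              # (H*W) x B

  # age tilt: +a below 530 nm, -a at and above
  a <- p$age_slope * (p$age - 60)
  tilt <- ifelse(grid$nm < 530, a, -a)
  flat <- sweep(flat, 2, tilt, "+")

  # case signal inside the window
  if (p$label == "hcq" && p$delta != 0) {
    idx <- window_index(grid, p$window)
    if (p$spatial_extent == "global") {
      flat[, idx] <- flat[, idx] * (1 + p$delta)
    } else {
      mult <- 1 + p$delta * as.numeric(maps$fovea)
      flat[, idx] <- flat[, idx] * mult
    }
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  # per-scene smooth confounder, concentrated outside the window
  if (p$nuisance_sd > 0) {
    amp <- stats::rnorm(1, 0, p$nuisance_sd)
    flat <- flat * rep(1 + amp * nuisance_shape(grid), each = nrow(flat))
  }
  if (p$noise_sd > 0) {
    flat <- flat + stats::rnorm(length(flat), 0, p$noise_sd)
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  cube <- new_reflectance_cube(array(pmin(pmax(flat, 0), 1), c(H, W, B)), grid)
  covs <- utils::modifyList(list(age = p$age, sex = NA, hbp = NA,
                                 glaucoma = NA, amd = NA, dr_stage = NA),
                            p$covariates)
  structure(
    list(cube = cube,
         landmarks = list(fovea_center = p$fovea_center,
                          disc_center = p$disc_center,
                          arcade_half_height = p$arcade_half_height),
         label = p$label, covariates = covs, seed = as.integer(seed),
         params = p),
    class = "reflectance_scene"
  )
}

#' @export
print.reflectance_scene <- function(x, ...) {
  d <- dim(x$cube)
  cat(sprintf("<reflectance_scene> %d x %d x %d, label = %s, age = %g, seed = %d\n",
              d[1], d[2], d[3], x$label, x$covariates$age, x$seed))
  invisible(x)
}
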