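# Band-selected color reproduction (cube -> 3-channel image) and the
# augmentation operators used for data amplification.
#
# Reproduction applies a hard indicator of the wavelength window (boxcar
# band selection), integrates against illuminant x observer weights, and
# white-balances against the window-restricted white point so band-limited
# images are not uniformly dark or color-cast.

#' Configuration for band-selected color reproduction
#'
#' @param window Wavelength window `c(lo, hi)` in nm (default 500-600).
#' @param output_size Optional `c(H, W)` to resize to (bilinear); `NULL`
#'   keeps the cube's spatial size.
#' @return A `repro_config` list.
#' @export
repro_config <- function(window = c(500, 600), output_size = NULL) {
  stopifnot(length(window) == 2, window[1] < window[2])
  if (!is.null(output_size)) stopifnot(length(output_size) == 2,
                                       all(output_size >= 1))
  structure(list(window = window, output_size = output_size),
            class = "repro_config")
}

# unnormalized window luminance: sum over window of R * S * ybar * step
window_luminance <- function(cube, camera, window) {
  idx <- window_index(camera$grid, window)
  d <- dim(cube)
  w <- camera$illuminant[idx] * camera$cmf["y", idx] * camera$grid$step
  matrix(cube_spectra(cube)[, idx, drop = FALSE] %*% w, d[1], d[2])
}

#' Reproduce a 3-channel image from a band-selected reflectance cube
#'
#' Spectra are multiplied by the window indicator, integrated against the
#' camera's illuminant and color-matching weights normalized over the
#' window, white-balanced against the window-restricted white point,
#' gamma-encoded, optionally resized, and quantized to 8 bits. With the
#' full-grid window this reduces to the direct camera rendering.
#'
#' @param cube A `reflectance_cube`.
#' @param camera A [make_camera_model()] on the cube's grid.
#' @param cfg A [repro_config()].
#' @return A `fundus_image` (8-bit, exactly 3 channels).
#' @export
reproduce_color <- function(cube, camera, cfg = repro_config()) {
  grid <- cube_grid(cube)
  if (!grids_identical(grid, camera$grid)) stop("cube and camera grids differ")
  idx <- window_index(grid, cfg$window)
  if (length(idx) == 0) stop("empty band window")
  d <- dim(cube)
  k_win <- sum(camera$illuminant[idx] * camera$cmf["y", idx]) * grid$step
  spectra_win <- cube_spectra(cube)[, idx, drop = FALSE]
  xyz <- camera_xyz(spectra_win, camera, band_idx = idx, k_norm = k_win)
  white_xyz <- as.numeric(camera$cmf[, idx, drop = FALSE] %*%
                            camera$illuminant[idx]) * grid$step / k_win
  if (any(white_xyz <= 0)) stop("degenerate window white point")
  enc <- array(xyz_to_encoded_rgb(xyz, white_xyz), c(d[1], d[2], 3))
  if (!is.null(cfg$output_size) && !all(cfg$output_size == d[1:2])) {
    enc <- resize_array(enc, cfg$output_size)
  }
  img <- array(as.integer(round_half_away(pmin(pmax(enc, 0), 1) * 255)),
               dim = c(dim(enc)[1], dim(enc)[2], 3))
  new_fundus_image(img)
}

# --- 8-bit image <-> EBImage helpers ---------------------------------------

to_ebimage <- function(img8) {
  EBImage::Image(aperm(img8 / 255, c(2, 1, 3)), colormode = "Color")
}

from_ebimage <- function(ebi) {
  a <- aperm(as.array(ebi), c(2, 1, 3))
  array(as.integer(round_half_away(pmin(pmax(a, 0), 1) * 255)), dim = dim(a))
}

# bilinear resize of an H x W x C [0,1] array
resize_array <- function(a, size) {
  ebi <- EBImage::Image(aperm(a, c(2, 1, 3)), colormode = "Color")
  out <- EBImage::resize(ebi, w = size[2], h = size[1])
  aperm(as.array(out), c(2, 1, 3))
}

rot90_cw <- function(m) t(m)[, nrow(m):1, drop = FALSE]

rotate_exact <- function(img, angle) {
  k <- (angle / 90) %% 4
  out <- img
  for (i in seq_len(k)) {
    d <- dim(out)
    out <- array(apply(out, 3, rot90_cw), c(d[2], d[1], d[3]))
  }
  out
}

# arbitrary-angle rotation with reflective padding, same output size
rotate_reflective <- function(img8, angle) {
  d <- dim(img8)
  m <- ceiling(max(d[1:2]) * 0.3)
  ri <- c(m:1, 1:d[1], d[1]:(d[1] - m + 1))
  ci <- c(m:1, 1:d[2], d[2]:(d[2] - m + 1))
  pad <- img8[ri, ci, , drop = FALSE]
  rot <- EBImage::rotate(to_ebimage(pad), angle,
                         output.dim = dim(pad)[2:1], bg.col = "black")
  out <- from_ebimage(rot)
  out[(m + 1):(m + d[1]), (m + 1):(m + d[2]), , drop = FALSE]
}

.AUGMENT_OPS <- c("hflip", "vflip", "rotate", "clahe", "gaussian_blur",
                  "green_channel")

#' Apply one augmentation operator to an 8-bit image
#'
#' Supported ops: `hflip`, `vflip`, `rotate` (angle 90/180/270 exact, other
#' angles via reflective padding), `clahe` (contrast-limited adaptive
#' histogram equalization; clip limit 2, 8x8 tiles by default),
#' `gaussian_blur` (`sigma`, default 1), `green_channel` (green plane
#' replicated to 3 channels). Spatial size and any label metadata are
#' preserved. `rotate` without an explicit `angle` samples one of 90/180/270
#' using `seed`.
#'
#' @param image 8-bit `H x W x 3` array.
#' @param op_name One of the supported operator names.
#' @param params Named list of operator parameters.
#' @param seed Integer seed used when an operator samples a parameter.
#' @return The augmented image, same dimensions and attributes.
#' @export
augment <- function(image, op_name, params = list(), seed = 1) {
  if (!op_name %in% .AUGMENT_OPS) {
    stop("unknown augmentation op '", op_name, "'; expected one of: ",
         paste(.AUGMENT_OPS, collapse = ", "))
  }
  d <- dim(image)
  stopifnot(length(d) == 3, d[3] == 3)
  px <- array(as.integer(image), d)
  out <- switch(
    op_name,
    hflip = px[, d[2]:1, , drop = FALSE],
    vflip = px[d[1]:1, , , drop = FALSE],
    rotate = {
      angle <- params$angle
      if (is.null(angle)) {
        old_seed <- get0(".Random.seed", envir = globalenv())
        set.seed(as.integer(seed))
        angle <- sample(c(90, 180, 270), 1)
        if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
      }
      if (angle %% 90 == 0) {
        if (angle %% 180 != 0 && d[1] != d[2]) {
          stop("90/270-degree rotation requires a square image")
        }
        rotate_exact(px, angle)
      } else {
        rotate_reflective(px, angle)
      }
    },
    clahe = {
      nx <- params$nx %||% 8; ny <- params$ny %||% 8
      clip <- params$clip_limit %||% 2
      from_ebimage(EBImage::clahe(to_ebimage(px), nx = nx, ny = ny,
                                  limit = clip))
    },
    gaussian_blur = {
      sigma <- params$sigma %||% 1
      # kernel must fit inside the image: largest odd radius <= min dim
      r <- min(2 * ceiling(3 * sigma) + 1, 2 * ((min(d[1:2]) - 1) %/% 2) + 1)
      from_ebimage(EBImage::gblur(to_ebimage(px), sigma = sigma, radius = r))
    },
    green_channel = {
      g <- px[, , 2]
      array(g, c(d[1], d[2], 3))
    }
  )
  attributes(out)$dim <- d
  for (at in c("class", "landmarks", "label", "covariates", "image_id")) {
    attr(out, at) <- attr(image, at, exact = TRUE)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# format / parse op chains like "rotate(angle=270)|gaussian_blur(sigma=1)"
format_op <- function(op, params) {
  if (length(params) == 0) return(op)
  sprintf("%s(%s)", op,
          paste(sprintf("%s=%g", names(params), unlist(params)), collapse = ","))
}

parse_op_chain <- function(chain) {
  if (is.na(chain) || chain == "") return(list())
  lapply(strsplit(chain, "|", fixed = TRUE)[[1]], function(tok) {
    m <- regmatches(tok, regexec("^([a-z_]+)(?:\\(([^)]*)\\))?$", tok))[[1]]
    if (length(m) == 0) stop("cannot parse op token: ", tok)
    params <- list()
    if (!is.na(m[3]) && nzchar(m[3])) {
      for (kv in strsplit(m[3], ",", fixed = TRUE)[[1]]) {
        p <- strsplit(kv, "=", fixed = TRUE)[[1]]
        params[[p[1]]] <- as.numeric(p[2])
      }
    }
    list(op = m[2], params = params)
  })
}

#' Re-apply a recorded augmentation chain
#'
#' @param image 8-bit image array.
#' @param chain Chain string from a dataset manifest, e.g.
#'   `"rotate(angle=270)|gaussian_blur(sigma=1)"`.
#' @return The transformed image.
#' @export
apply_op_chain <- function(image, chain) {
  for (step in parse_op_chain(chain)) {
    image <- augment(image, step$op, step$params)
  }
  image
}

#' Build an augmented dataset with a manifest
#'
#' Applies each augmentation op in `pipeline_spec`, with its multiplicity,
#' to every training-split source image, writes the derived PNGs to
#' `out_dir`, and returns a manifest recording provenance. Only the training
#' split is ever augmented; requesting augmentation of the test split is an
#' error (leakage guard). Sampled parameters (e.g. rotation angles) are
#' resolved at build time and recorded in the chain, so any derived file can
#' be reproduced from its source and manifest row alone.
#'
#' @param images Data frame with columns `image_id`, `file` (PNG path),
#'   `label`, `split` (`"train"`/`"test"`).
#' @param pipeline_spec List of op entries: `list(op =, multiplicity =,
#'   params = list())`.
#' @param seed Integer seed for sampled op parameters.
#' @param out_dir Directory for derived images.
#' @param augment_split Split to augment; anything but `"train"` errors.
#' @return Manifest data frame: `file`, `source_id`, `label`, `split`,
#'   `op_chain` (empty for source rows).
#' @export
build_dataset <- function(images, pipeline_spec, seed = 1,
                          out_dir = tempfile("aug"),
                          augment_split = "train") {
  stopifnot(all(c("image_id", "file", "label", "split") %in% names(images)))
  if (!identical(augment_split, "train")) {
    stop("augmentation is restricted to the training split (test-set leakage guard)")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(file = images$file, source_id = images$image_id,
                         label = images$label, split = images$split,
                         op_chain = "", stringsAsFactors = FALSE)
  train <- images[images$split == "train", , drop = FALSE]
  derived <- list()
  counter <- 0L
  for (i in seq_len(nrow(train))) {
    src <- read_image_png(train$file[i])
    for (entry in pipeline_spec) {
      mult <- entry$multiplicity %||% 1
      for (mcopy in seq_len(mult)) {
        counter <- counter + 1L
        params <- entry$params %||% list()
        if (entry$op == "rotate" && is.null(params$angle)) {
          old_seed <- get0(".Random.seed", envir = globalenv())
          set.seed(as.integer(seed) + counter)
          params$angle <- sample(c(90, 180, 270), 1)
          if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
        }
        chain <- format_op(entry$op, params)
        out <- augment(src, entry$op, params)
        fn <- file.path(out_dir, sprintf("%s_aug%04d.png", train$image_id[i],
                                         counter))
        write_image_png(out, fn)
        derived[[length(derived) + 1L]] <- data.frame(
          file = fn, source_id = train$image_id[i], label = train$label[i],
          split = "train", op_chain = chain, stringsAsFactors = FALSE)
      }
    }
  }
  rbind(manifest, do.call(rbind, derived))
}
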