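# File formats: 8-bit PNG for images, 32-bit float multi-page TIFF for
# reflectance cubes (one page per band) with a JSON sidecar carrying the
# wavelength attributes, CSV for tables.

#' Read / write an 8-bit RGB image as PNG
#'
#' @param path PNG file path.
#' @return `read_image_png` returns an integer `H x W x 3` array in 0..255.
#' @export
read_image_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  if (dim(a)[3] == 4) a <- a[, , 1:3, drop = FALSE]
  array(as.integer(round_half_away(a * 255)), dim = dim(a))
}

#' @param image Integer `H x W x 3` array in 0..255.
#' @rdname read_image_png
#' @export
write_image_png <- function(image, path) {
  png::writePNG(array(image / 255, dim = dim(image)), path)
  invisible(path)
}

#' Write / read a reflectance cube as multi-page float TIFF
#'
#' One 32-bit float page per band; a `<path>.json` sidecar stores
#' `wavelength_start`, `wavelength_stop`, `wavelength_step`.
#'
#' @param cube A `reflectance_cube`.
#' @param path Output `.tif` path.
#' @export
write_cube <- function(cube, path) {
  g <- cube_grid(cube)
  pages <- lapply(seq_len(dim(cube)[3]), function(b) cube[, , b])
  tiff::writeTIFF(pages, path, bits.per.sample = 32)
  jsonlite::write_json(
    list(wavelength_start = g$start, wavelength_stop = g$stop,
         wavelength_step = g$step, dataset = "reflectance"),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cube
#' @return `read_cube` returns the `reflectance_cube`.
#' @export
read_cube <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  grid <- wavelength_grid(meta$wavelength_start, meta$wavelength_stop,
                          meta$wavelength_step)
  pages <- tiff::readTIFF(path, all = TRUE)
  a <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  new_reflectance_cube(a, grid)
}

#' Write / read a cohort table as CSV
#'
#' @param cohort A `cohort_table` data frame.
#' @param path CSV path.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Write a landmarks table as CSV
#'
#' Columns: `image_id, fovea_row, fovea_col, disc_row, disc_col,
#' arcade_half_height`.
#'
#' @param landmarks Data frame in the layout above.
#' @param path CSV path.
#' @export
write_landmarks_csv <- function(landmarks, path) {
  utils::write.csv(landmarks, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks_csv
#' @export
read_landmarks_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a color checker as CSV
#'
#' One row per patch: `R, G, B` (8-bit) followed by the reflectance at each
#' band (`nm380` ... `nm780`).
#'
#' @param checker A [generate_checker()] result.
#' @param path CSV path.
#' @export
write_checker_csv <- function(checker, path) {
  df <- data.frame(checker$patch_rgb,
                   checker$patch_spectra)
  names(df) <- c("R", "G", "B", paste0("nm", checker$grid$nm))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_checker_csv
#' @param grid Wavelength grid the spectra columns are on.
#' @export
read_checker_csv <- function(path, grid = wavelength_grid()) {
  df <- utils::read.csv(path)
  structure(
    list(patch_spectra = as.matrix(df[, paste0("nm", grid$nm)]),
         patch_rgb = as.matrix(df[, c("R", "G", "B")]),
         grid = grid),
    class = "color_checker"
  )
}
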