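test_that("reproduction yields 3 channels and maps zero cubes to black", {
  cam <- get_camera()
  cube <- get_clean_scene()$scene$cube
  img <- reproduce_color(cube, cam, repro_config())
  expect_equal(dim(img)[3], 3)
  expect_equal(dim(img)[1:2], dim(cube)[1:2])
  zero <- fundusHSI:::new_reflectance_cube(array(0, c(4, 4, 401)), cam$grid)
  expect_true(all(reproduce_color(zero, cam, repro_config()) == 0))
  expect_error(repro_config(window = c(600, 500)))
})

test_that("full-window reproduction equals the direct camera render", {
  cam <- get_camera()
  cube <- get_clean_scene()$scene$cube
  direct <- render(cube, cam)
  full <- reproduce_color(cube, cam, repro_config(window = c(380, 780)))
  expect_lte(max(abs(unclass(direct) - unclass(full))), 2)
})

test_that("reproduction resizes to a requested output size", {
  cam <- get_camera()
  cube <- get_clean_scene()$scene$cube
  img <- reproduce_color(cube, cam, repro_config(output_size = c(32, 32)))
  expect_equal(dim(img), c(32, 32, 3))
})

test_that("widening the window never decreases pre-balance luminance", {
  cam <- get_camera()
  cube <- get_clean_scene()$scene$cube
  widths <- list(c(520, 580), c(500, 600), c(450, 650), c(380, 780))
  lum <- lapply(widths, function(w) fundusHSI:::window_luminance(cube, cam, w))
  for (i in seq_len(length(widths) - 1)) {
    expect_true(all(lum[[i + 1]] - lum[[i]] >= -1e-12))
  }
})

test_that("flips are involutions and rotations cycle exactly", {
  img <- get_clean_scene()$image
  expect_identical(unclass(augment(augment(img, "hflip"), "hflip")),
                   unclass(img))
  expect_identical(unclass(augment(augment(img, "vflip"), "vflip")),
                   unclass(img))
  r90 <- augment(img, "rotate", list(angle = 90))
  r360 <- augment(augment(r90, "rotate", list(angle = 180)),
                  "rotate", list(angle = 90))
  expect_identical(unclass(r360), unclass(img))
  expect_identical(unclass(augment(img, "rotate", list(angle = 180))),
                   unclass(augment(augment(img, "hflip"), "vflip")))
  expect_error(augment(img, "sharpen"), "unknown augmentation op")
})

test_that("clahe leaves a constant image constant and green_channel replicates", {
  const <- array(120L, c(32, 32, 3))
  eq <- augment(const, "clahe")
  expect_equal(dim(eq), c(32, 32, 3))
  for (ch in 1:3) expect_equal(length(unique(as.integer(eq[, , ch]))), 1)
  img <- get_clean_scene()$image
  g <- augment(img, "green_channel")
  expect_identical(g[, , 1], g[, , 2])
  expect_identical(g[, , 3], unclass(img)[, , 2])
})

test_that("augmentation preserves dimensions and label metadata", {
  img <- get_clean_scene()$image
  for (op in c("hflip", "vflip", "clahe", "gaussian_blur", "green_channel")) {
    out <- augment(img, op)
    expect_equal(dim(out), dim(img))
    expect_identical(attr(out, "label"), attr(img, "label"))
  }
})

test_that("dataset building augments only the training split, reproducibly", {
  td <- tempfile("ds"); dir.create(td)
  img_files <- character(0)
  for (i in 1:6) {
    sc <- generate_scene(scene_params(size = c(32, 32)), seed = 100 + i)
    fn <- file.path(td, sprintf("img%d.png", i))
    write_image_png(render(sc, get_camera()), fn)
    img_files <- c(img_files, fn)
  }
  images <- data.frame(
    image_id = sprintf("img%d", 1:6), file = img_files,
    label = rep(c("hcq", "normal"), 3),
    split = rep(c("train", "test"), c(4, 2)), stringsAsFactors = FALSE)
  spec <- list(list(op = "hflip", multiplicity = 1),
               list(op = "rotate", multiplicity = 3))
  man <- build_dataset(images, spec, seed = 5, out_dir = file.path(td, "aug"))
  derived <- man[man$op_chain != "", ]
  expect_equal(nrow(derived), 4 * (1 + 3))     # sources x multiplicities
  expect_true(all(derived$split == "train"))
  # identical seed regenerates an identical manifest
  man2 <- build_dataset(images, spec, seed = 5, out_dir = file.path(td, "aug2"))
  expect_equal(man$op_chain, man2$op_chain)
  expect_equal(man$source_id, man2$source_id)
  # re-applying each recorded chain reproduces the stored file bit for bit
  for (i in sample(seq_len(nrow(derived)), 4)) {
    src <- read_image_png(images$file[images$image_id == derived$source_id[i]])
    redo <- apply_op_chain(src, derived$op_chain[i])
    expect_identical(tools::md5sum(derived$file[i])[[1]],
                     {tmp <- tempfile(fileext = ".png")
                      write_image_png(redo, tmp)
                      tools::md5sum(tmp)[[1]]})
  }
  expect_error(build_dataset(images, spec, augment_split = "test"), "leakage")
})
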