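test_that("scenes are deterministic, clipped, and carry their landmarks", {
  p <- scene_params(size = c(32, 32))
  a <- generate_scene(p, seed = 5)
  b <- generate_scene(p, seed = 5)
  expect_identical(unclass(a$cube), unclass(b$cube))
  expect_true(all(a$cube >= 0 & a$cube <= 1))
  expect_equal(dim(a$cube), c(32, 32, 401))
  expect_equal(a$landmarks$fovea_center, c(16, 0.6 * 32))
  c2 <- generate_scene(p, seed = 6)
  expect_false(identical(unclass(a$cube), unclass(c2$cube)))
})

test_that("the case signal is confined to the configured window", {
  base <- list(size = c(24, 24), noise_sd = 0, delta = 0.05)
  pn <- do.call(scene_params, c(base, list(label = "normal")))
  ph <- do.call(scene_params, c(base, list(label = "hcq")))
  sn <- generate_scene(pn, seed = 3)
  sh <- generate_scene(ph, seed = 3)
  idx <- fundusHSI:::window_index(pn$grid, c(500, 600))
  expect_identical(unclass(sn$cube)[, , -idx], unclass(sh$cube)[, , -idx])
  expect_true(all(sh$cube[, , idx] >= sn$cube[, , idx]))
  expect_gt(max(sh$cube[, , idx] - sn$cube[, , idx]), 0)
  expect_error(scene_params(window = c(900, 1000)), "outside the grid")
})

test_that("the mean case-control spectral difference peaks inside 500-600 nm", {
  # Monte-Carlo oracle over generated scenes (reduced corpus; the full-size
  # recovery check lives with the band-selection acceptance test)
  g <- wavelength_grid()
  n <- 50
  acc <- matrix(0, 2, g$count)
  for (i in seq_len(n)) {
    for (li in 1:2) {
      lab <- c("hcq", "normal")[li]
      p <- scene_params(label = lab, age = 65 + (i * 7) %% 20, delta = 0.05,
                        size = c(16, 16))
      sc <- generate_scene(p, seed = 5000 + i * 2 + li)
      acc[li, ] <- acc[li, ] + colMeans(fundusHSI:::cube_spectra(sc$cube))
    }
  }
  d <- abs(acc[1, ] - acc[2, ]) / n
  expect_true(g$nm[which.max(d)] >= 500 && g$nm[which.max(d)] <= 600)
})

test_that("checker has 24 canonical patches plus extras, all smooth in [0,1]", {
  cam <- get_camera()
  ck0 <- generate_checker(cam, n_extra = 0)
  expect_equal(nrow(ck0$patch_spectra), 24)
  ck <- get_checker()
  expect_equal(nrow(ck$patch_spectra), 124)
  expect_true(all(ck$patch_spectra >= 0 & ck$patch_spectra <= 1))
  expect_lt(checker_smoothness(ck), 2e-3)
  # patch RGB is exactly the camera rendering of the patch spectra
  expect_identical(ck$patch_rgb,
                   fundusHSI:::render_spectra(ck$patch_spectra, cam))
  expect_identical(generate_checker(cam, 20, seed = 9)$patch_spectra,
                   generate_checker(cam, 20, seed = 9)$patch_spectra)
})

test_that("cohort generation reproduces the reference counts exactly", {
  co <- generate_cohort(25, 66, seed = 11, table1_mode = TRUE)
  expect_equal(nrow(co), 91)
  ref <- cohort_reference_counts()
  h <- co[co$group == "hcq", ]; n <- co[co$group == "normal", ]
  expect_equal(unname(table(factor(h$sex, c("female", "male")))), c(22, 3),
               ignore_attr = TRUE)
  expect_equal(unname(table(factor(n$sex, c("female", "male")))), c(45, 21),
               ignore_attr = TRUE)
  expect_equal(sum(h$hbp == "pos"), 17); expect_equal(sum(n$hbp == "pos"), 59)
  expect_equal(sum(h$glaucoma == "pos"), 6); expect_equal(sum(n$glaucoma == "pos"), 12)
  expect_equal(sum(h$amd == "pos"), 17); expect_equal(sum(n$amd == "pos"), 49)
  expect_equal(unname(table(factor(h$dr_stage, c("normal", "BDR", "PDR", "PPDR")))),
               c(6, 6, 4, 9), ignore_attr = TRUE)
  expect_equal(unname(table(factor(n$dr_stage, c("normal", "BDR", "PDR", "PPDR")))),
               c(21, 11, 18, 16), ignore_attr = TRUE)
  expect_error(generate_cohort(10, 10, seed = 1, table1_mode = TRUE),
               "default group sizes")
})

test_that("cohort ages follow the configured group distributions", {
  co <- generate_cohort(1, 1, seed = 2)
  expect_equal(nrow(co), 2)
  expect_setequal(co$group, c("hcq", "normal"))
  big <- generate_cohort(10000, 10000, seed = 3)
  ref <- cohort_reference_counts()
  expect_lt(abs(mean(big$age[big$group == "hcq"]) - ref$age_mean["hcq"]), 0.5)
  expect_lt(abs(mean(big$age[big$group == "normal"]) - ref$age_mean["normal"]),
            0.5)
  expect_identical(generate_cohort(25, 66, seed = 4),
                   generate_cohort(25, 66, seed = 4))
})
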