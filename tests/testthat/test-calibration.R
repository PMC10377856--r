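test_that("polynomial features enumerate all degree-<=3 monomials", {
  f0 <- poly_features(c(0, 0, 0))
  expect_equal(length(f0), 20)
  expect_equal(f0, c(1, rep(0, 19)))
  expect_equal(poly_features(c(1, 1, 1)), rep(1, 20))
  # spot-check against the documented order on an asymmetric point
  f <- poly_features(c(2, 3, 5))
  expect_equal(f[1:4], c(1, 2, 3, 5))         # 1, X, Y, Z
  expect_equal(f[5], 4)                       # X^2
  expect_equal(f[length(f)], 125)             # Z^3 last
  m <- poly_features(rbind(c(0, 0, 0), c(1, 1, 1)))
  expect_equal(dim(m), c(2, 20))
})

test_that("calibration fits the synthetic checker to tight training error", {
  calib <- get_calibration()
  expect_lte(calib$fit_report$train_rmse, 0.02)
  expect_equal(calib$k, 12)
  # basis columns orthonormal
  expect_equal(crossprod(calib$basis), diag(12), tolerance = 1e-10)
  # training RMSE is non-increasing in k
  rk <- vapply(c(2, 4, 8, 12), function(k)
    fit_calibration(get_checker(), get_camera(), k = k)$fit_report$train_rmse,
    numeric(1))
  expect_true(all(diff(rk) <= 1e-12))
})

test_that("a complete basis with interpolating features reconstructs exactly", {
  cam <- get_camera()
  # exactly 20 distinct patches: as many as polynomial features
  sp <- get_checker()$patch_spectra[c(1:12, 30:37), ]
  ck <- structure(list(patch_spectra = sp,
                       patch_rgb = fundusHSI:::render_spectra(sp, cam),
                       grid = cam$grid), class = "color_checker")
  m <- fit_calibration(ck, cam, k = 20, lambda = 0)
  expect_lt(m$fit_report$train_rmse, 1e-8)
})

test_that("calibration guards its preconditions", {
  cam <- get_camera()
  sp <- get_checker()$patch_spectra[1:10, ]
  ck <- structure(list(patch_spectra = sp,
                       patch_rgb = fundusHSI:::render_spectra(sp, cam),
                       grid = cam$grid), class = "color_checker")
  expect_error(fit_calibration(ck, cam, k = 5), "at least 20")
  expect_error(fit_calibration(get_checker(), cam, k = 200), "cannot exceed")
})

test_that("held-out smooth spectra reconstruct below 0.05 RMSE (leave-one-out)", {
  cam <- get_camera()
  ck <- get_checker()
  heldout <- seq(30, 108, by = 2)          # 40 of the random patches
  loo <- vapply(heldout, function(i) {
    sub <- structure(list(patch_spectra = ck$patch_spectra[-i, ],
                          patch_rgb = ck$patch_rgb[-i, ],
                          grid = ck$grid), class = "color_checker")
    m <- fit_calibration(sub, cam, k = 12)
    est <- fundusHSI:::reconstruct_spectra(ck$patch_rgb[i, , drop = FALSE], m)
    sqrt(mean((est - ck$patch_spectra[i, ])^2))
  }, numeric(1))
  expect_lt(mean(loo), 0.05)
})

test_that("rgb_to_cube honors the shape contract and color-function property", {
  calib <- get_calibration()
  img <- array(as.integer(c(10, 200, 30)), c(1, 1, 3))
  img <- img[rep(1, 4), rep(1, 5), , drop = FALSE]   # 4 x 5, constant color
  cube <- rgb_to_cube(img, calib)
  expect_equal(dim(cube), c(4, 5, 401))
  # metamer honesty: identical colors -> identical spectra
  flat <- fundusHSI:::cube_spectra(cube)
  expect_true(all(apply(flat, 2, function(col) length(unique(col)) == 1)))
  # all-black image: every pixel equals the documented closed-form spectrum
  black <- array(0L, c(2, 2, 3))
  bc <- rgb_to_cube(black, calib)
  phi <- poly_features(poly_features(srgb_to_tristimulus(c(0, 0, 0))) %*%
                         calib$color_correction)
  want <- pmin(pmax(calib$basis_mean +
                      as.numeric(calib$basis %*% t(phi %*% calib$score_map)), 0), 1)
  expect_equal(as.numeric(bc[1, 1, ]), want, tolerance = 1e-12)
  expect_error(rgb_to_cube(black, list()), "fit_calibration")
})

test_that("render -> convert round trip stays within 0.05 reflectance RMSE", {
  fx <- get_clean_scene()
  est <- rgb_to_cube(fx$image, get_calibration())
  expect_equal(dim(est)[3], 401)
  expect_true(all(est >= 0 & est <= 1))
  expect_lte(reconstruction_rmse(est, fx$scene$cube), 0.05)
})

test_that("reconstruction RMSE matches an elementwise oracle", {
  expect_equal(reconstruction_rmse(array(0.5, c(2, 2, 5)),
                                   array(0.6, c(2, 2, 5))), 0.1)
  a <- array(0, c(2, 2, 3)); expect_equal(reconstruction_rmse(a, a), 0)
  set.seed(8)
  x <- array(runif(60), c(3, 4, 5)); y <- array(runif(60), c(3, 4, 5))
  oracle <- sqrt(sum((x - y)^2) / 60)
  expect_equal(reconstruction_rmse(x, y), oracle, tolerance = 1e-12)
  expect_error(reconstruction_rmse(x, array(0, c(3, 4, 6))), "shapes differ")
})
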