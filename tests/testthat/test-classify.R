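test_that("stratified split reproduces the published data distribution", {
  labels <- rep(c("normal", "hcq"), c(66, 110))
  sp <- stratified_split(labels, 0.8, seed = 3)
  expect_equal(sp$counts["normal", ], c(train = 53, test = 13, total = 66))
  expect_equal(sp$counts["hcq", ], c(train = 88, test = 22, total = 110))
  expect_equal(length(intersect(sp$train, sp$test)), 0)
  expect_error(stratified_split(labels, 1.0), "strictly between")
  expect_error(stratified_split(rep("a", 5)), "2 classes")
})

test_that("split conservation holds over fractions and seeds", {
  set.seed(91)
  for (i in 1:10) {
    n1 <- sample(5:40, 1); n2 <- sample(5:40, 1)
    labels <- sample(rep(c("x", "y"), c(n1, n2)))
    f <- runif(1, 0.2, 0.9)
    sp <- stratified_split(labels, f, seed = i)
    expect_equal(sp$counts[, "train"] + sp$counts[, "test"],
                 sp$counts[, "total"])
    expect_equal(unname(sp$counts["x", "total"]), n1)
    expect_identical(stratified_split(labels, f, seed = i)$train, sp$train)
  }
})

test_that("grouped splitting never lets a subject span both sides", {
  labels <- rep(c("hcq", "normal"), c(40, 24))
  groups <- c(rep(sprintf("h%02d", 1:10), each = 4),
              rep(sprintf("n%02d", 1:12), each = 2))
  for (s in 1:5) {
    sp <- stratified_split(labels, 0.8, seed = s, group_ids = groups)
    expect_equal(length(intersect(unique(groups[sp$train]),
                                  unique(groups[sp$test]))), 0)
    expect_gt(length(sp$train), 0); expect_gt(length(sp$test), 0)
  }
})

test_that("confusion-matrix metrics match hand arithmetic and identities", {
  lv <- c("hcq", "normal")
  cm <- matrix(c(22, 0, 0, 13), 2, byrow = TRUE, dimnames = list(lv, lv))
  perfect <- metrics_from_confusion(cm)
  for (f in c("accuracy", "precision", "recall", "specificity", "f1")) {
    expect_equal(perfect[[f]], 1)
  }
  cm2 <- matrix(c(20, 2, 1, 12), 2, byrow = TRUE, dimnames = list(lv, lv))
  m <- metrics_from_confusion(cm2)
  expect_equal(m$accuracy, 32 / 35)
  expect_equal(m$precision, 20 / 21)
  expect_equal(m$recall, 20 / 22)
  expect_equal(m$specificity, 12 / 13)
  # accuracy identity: (recall*P + specificity*N) / (P + N)
  expect_equal(m$accuracy, (m$recall * 22 + m$specificity * 13) / 35)
  expect_error(metrics_from_confusion(matrix(0, 2, 2,
                                             dimnames = list(lv, lv))),
               "non-empty")
})

test_that("metrics agree with a per-sample recount on random label vectors", {
  set.seed(101)
  lv <- c("hcq", "normal")
  for (i in 1:10) {
    n <- 50
    truth <- sample(lv, n, replace = TRUE)
    pred <- sample(lv, n, replace = TRUE)
    cm <- table(factor(truth, lv), factor(pred, lv))
    m <- metrics_from_confusion(unclass(as.matrix(cm)))
    expect_equal(m$accuracy, mean(truth == pred))
    tp <- sum(truth == "hcq" & pred == "hcq")
    if (sum(pred == "hcq") > 0) {
      expect_equal(m$precision, tp / sum(pred == "hcq"))
    }
    expect_equal(m$recall, tp / sum(truth == "hcq"))
  }
})

test_that("F1 is the harmonic mean with a degenerate-zero flag", {
  expect_equal(round(f1_from_pr(0.82, 0.75), 2), 0.78)
  expect_equal(round(f1_from_pr(0.98, 0.67), 2), 0.80)
  expect_equal(f1_from_pr(1, 1), 1)
  z <- f1_from_pr(0, 0)
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "degenerate"))
})

test_that("the learning-rate schedule decays stepwise every seven epochs", {
  cfg <- train_config()
  expect_equal(lr_at_epoch(cfg, 0), 0.001)
  expect_equal(lr_at_epoch(cfg, 6), 0.001)
  expect_equal(lr_at_epoch(cfg, 7), 0.0001)
  expect_equal(lr_at_epoch(cfg, 14), 0.00001)
  expect_error(train_config(architecture = "resnet50"), "compact_cnn")
})

test_that("training is reproducible, reaches high accuracy on a separable set, and epochs = 0 is a no-op", {
  cam <- get_camera()
  corp <- generate_separable_corpus(12, seed = 5, cam, get_calibration(),
                                    size = 32)
  d <- corp$hsi
  cfg <- smoke_config(seed = 2)
  m <- train_classifier(cfg, d)
  expect_gte(m$history$accuracy[nrow(m$history)], 0.95)
  # epoch-average loss decreases overall on the smoke corpus
  expect_lt(m$history$loss[nrow(m$history)], m$history$loss[1])
  m2 <- train_classifier(cfg, d)
  expect_identical(m$par, m2$par)
  m0 <- train_classifier(smoke_config(seed = 2, epochs = 0), d)
  expect_equal(nrow(m0$history), 0)
  rep0 <- evaluate_classifier(m0, d)
  expect_true(rep0$accuracy >= 0 && rep0$accuracy <= 1)
  expect_error(train_classifier(cfg, list(x = d$x[1:3], y = rep("hcq", 3))),
               "2 classes")
})

test_that("grad-cam is normalized, input-sized, and flags degenerate gradients", {
  cam <- get_camera()
  corp <- generate_separable_corpus(8, seed = 6, cam, get_calibration(),
                                    size = 32)
  m <- train_classifier(smoke_config(seed = 3, epochs = 4), corp$hsi)
  hm <- grad_cam(m, corp$hsi$x[[1]])
  expect_equal(dim(hm), c(32, 32))
  expect_true(all(hm >= 0 & hm <= 1))
  expect_error(grad_cam(m, corp$hsi$x[[1]], class = "nope"), "unknown class")
  # zero head weights => uniformly zero gradients => flagged all-zero map
  m$par$Wd[] <- 0
  hm0 <- grad_cam(m, corp$hsi$x[[1]], class = "hcq")
  expect_true(all(hm0 == 0))
  expect_true(attr(hm0, "degenerate"))
})

test_that("grad-cam mass concentrates on the fovea for fovea-localized disease", {
  cam <- get_camera()
  xs <- list(); y <- character(0)
  for (i in 1:40) {
    lab <- if (i <= 20) "hcq" else "normal"
    p <- scene_params(label = lab, age = 75, delta = 0.8,
                      spatial_extent = "fovea", noise_sd = 0.01,
                      size = c(48, 48))
    xs[[i]] <- unclass(render(generate_scene(p, seed = 100 + i), cam))
    y <- c(y, lab)
  }
  m <- train_classifier(smoke_config(seed = 1), list(x = xs, y = y))
  expect_gte(m$history$accuracy[nrow(m$history)], 0.95)
  s <- m$cfg$input_size
  rows <- matrix(seq_len(s), s, s); cols <- t(rows)
  inside <- sqrt((rows - 0.5 * s)^2 + (cols - 0.6 * s)^2) <= 0.15 * s
  ratios <- vapply(1:4, function(k) {
    p <- scene_params(label = "hcq", delta = 0.8, spatial_extent = "fovea",
                      noise_sd = 0.01, size = c(48, 48))
    img <- unclass(render(generate_scene(p, seed = 2000 + k), cam))
    hm <- grad_cam(m, img)
    mean(hm[inside]) / mean(hm[!inside])
  }, numeric(1))
  expect_true(all(ratios > 1))
})
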