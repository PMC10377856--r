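# Paired ORI/HSI classification corpora.
#
# The smoke corpus realizes the study condition the classifier comparison is
# about: the case signal is confined to the 500-600 nm window while a strong
# smooth confounder lives just outside it (470/635 nm). The original renders
# (ORI) therefore carry the signal in a low-variance direction swamped by
# out-of-window variance; the band-selected reproductions (HSI) suppress the
# confounder, so a small-sample learner should do at least as well on HSI.

#' Generate a paired ORI/HSI image corpus from synthetic scenes
#'
#' For each scene: render the original RGB image (ORI), reconstruct the
#' spectral cube from that image with the supplied calibration, and
#' reproduce the band-selected image (HSI). Ages cycle deterministically
#' over 65-84 years.
#'
#' @param n_per_class Scenes per class (hcq / normal).
#' @param seed Integer seed; scene `i` uses seed `seed * 1000 + i`.
#' @param camera A [make_camera_model()].
#' @param calib A [fit_calibration()] model.
#' @param size Scene side length in pixels (default 48).
#' @param delta Case effect inside the window (default 0.08).
#' @param noise_sd Pixel noise (default 0.01).
#' @param nuisance_sd Out-of-window confounder amplitude sd (default 0.25).
#' @param window Case/reproduction window (default 500-600 nm).
#' @return List with elements `ori` and `hsi`, each `list(x = <images>,
#'   y = <labels>)`, plus `scenes_meta` (label, age, seed per scene).
#' @export
generate_smoke_corpus <- function(n_per_class, seed, camera, calib,
                                  size = 48, delta = 0.08, noise_sd = 0.01,
                                  nuisance_sd = 0.25, window = c(500, 600)) {
  rcfg <- repro_config(window = window)
  xs_ori <- vector("list", 2 * n_per_class)
  xs_hsi <- vector("list", 2 * n_per_class)
  y <- character(2 * n_per_class)
  meta <- NULL
  for (i in seq_len(2 * n_per_class)) {
    lab <- if (i <= n_per_class) "hcq" else "normal"
    age <- 65 + ((seed * 37 + i * 13) %% 20)
    p <- scene_params(label = lab, age = age, delta = delta,
                      noise_sd = noise_sd, nuisance_sd = nuisance_sd,
                      window = window, size = c(size, size))
    sc <- generate_scene(p, seed = (seed * 1000 + i) %% 2147483647)
    ori <- render(sc, camera)
    cube <- rgb_to_cube(ori, calib)
    xs_ori[[i]] <- unclass(ori)
    xs_hsi[[i]] <- unclass(reproduce_color(cube, camera, rcfg))
    y[i] <- lab
    meta <- rbind(meta, data.frame(label = lab, age = age,
                                   seed = seed * 1000 + i))
  }
  list(ori = list(x = xs_ori, y = y), hsi = list(x = xs_hsi, y = y),
       scenes_meta = meta)
}

#' Compare classifier accuracy on HSI vs ORI inputs over repeated seeds
#'
#' For each seed: generate a fresh paired corpus, split it 2:1 stratified,
#' train the smoke-configuration classifier separately on each variant, and
#' record train/test accuracy.
#'
#' @param seeds Integer vector of repetition seeds.
#' @param camera,calib Shared forward model and calibration.
#' @param n_per_class Scenes per class per repetition (default 30).
#' @param cfg_fn Function mapping a seed to a [train_config()]; defaults to
#'   [smoke_config()].
#' @param ... Passed to [generate_smoke_corpus()].
#' @return Data frame with one row per seed: `seed`, `ori_train`,
#'   `ori_test`, `hsi_train`, `hsi_test`, `hsi_ge_ori`.
#' @export
hsi_vs_ori_experiment <- function(seeds, camera, calib, n_per_class = 30,
                                  cfg_fn = function(s) smoke_config(seed = s),
                                  ...) {
  out <- NULL
  for (s in seeds) {
    corp <- generate_smoke_corpus(n_per_class, s, camera, calib, ...)
    sp <- stratified_split(corp$ori$y, 2 / 3, seed = s)
    acc <- sapply(c("ori", "hsi"), function(v) {
      d <- corp[[v]]
      m <- train_classifier(cfg_fn(s),
                            list(x = d$x[sp$train], y = d$y[sp$train]))
      c(train = m$history$accuracy[nrow(m$history)],
        test = evaluate_classifier(m, list(x = d$x[sp$test],
                                           y = d$y[sp$test]))$accuracy)
    })
    out <- rbind(out, data.frame(
      seed = s, ori_train = acc["train", "ori"], ori_test = acc["test", "ori"],
      hsi_train = acc["train", "hsi"], hsi_test = acc["test", "hsi"],
      hsi_ge_ori = acc["test", "hsi"] >= acc["test", "ori"]))
  }
  out
}

#' Generate a cleanly separable two-class corpus
#'
#' Noise-free scenes with a strong case effect: any reasonable learner
#' should fit the training set essentially perfectly. Used to validate the
#' training loop itself.
#'
#' @inheritParams generate_smoke_corpus
#' @export
generate_separable_corpus <- function(n_per_class, seed, camera, calib,
                                      size = 48) {
  generate_smoke_corpus(n_per_class, seed, camera, calib, size = size,
                        delta = 0.15, noise_sd = 0.002, nuisance_sd = 0)
}
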