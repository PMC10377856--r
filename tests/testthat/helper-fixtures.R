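# Shared fixtures, built once per test run. The camera model and the fitted
# calibration are deterministic, so caching them does not couple tests.

.fixtures <- new.env()

get_camera <- function() {
  if (is.null(.fixtures$camera)) .fixtures$camera <- make_camera_model()
  .fixtures$camera
}

get_checker <- function() {
  if (is.null(.fixtures$checker)) {
    .fixtures$checker <- generate_checker(get_camera(), n_extra = 100,
                                          seed = 42)
  }
  .fixtures$checker
}

get_calibration <- function() {
  if (is.null(.fixtures$calib)) {
    .fixtures$calib <- fit_calibration(get_checker(), get_camera(), k = 12)
  }
  .fixtures$calib
}

# a small clean scene and its render, reused by several files
get_clean_scene <- function() {
  if (is.null(.fixtures$scene)) {
    .fixtures$scene <- generate_scene(
      scene_params(size = c(48, 48), noise_sd = 0), seed = 7)
    .fixtures$render <- render(.fixtures$scene, get_camera())
  }
  list(scene = .fixtures$scene, image = .fixtures$render)
}
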