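# End-to-end runner: synthesize cohort + scenes -> render -> quality check ->
# calibrate -> convert -> ROI spectra -> band-window selection -> color
# reproduction -> split -> train -> evaluate -> report.json.
#
# Every stage writes its artifacts under the run directory; with
# `resume = TRUE` a stage whose artifact already exists is skipped and its
# output reloaded, so a run can be resumed stage by stage.

#' Pipeline configuration
#'
#' Defaults give a small but complete demonstration run. `roi_size` defaults
#' to the 240-pixel sampling patch scaled to the configured image size
#' (240/512 of the side length).
#'
#' @param out_dir Run directory.
#' @param n_hcq,n_normal Subjects per group.
#' @param images_per_subject Images per subject.
#' @param image_size Scene side length in pixels.
#' @param delta,window,noise_sd,nuisance_sd Scene generation parameters
#'   (see [scene_params()]).
#' @param roi_size ROI side length in pixels (`NULL`: scaled default).
#' @param checker_extra,k,ridge_lambda Calibration parameters.
#' @param width_nm Band-window width for selection.
#' @param split_fraction Training fraction.
#' @param train Training configuration, e.g. [smoke_config()].
#' @param augment_ops Optional augmentation pipeline spec (see
#'   [build_dataset()]); `NULL` disables augmentation.
#' @param seed Master seed.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("fundus_run"),
                            n_hcq = 10, n_normal = 10,
                            images_per_subject = 1, image_size = 64,
                            delta = 0.05, window = c(500, 600),
                            noise_sd = 0.005, nuisance_sd = 0,
                            roi_size = NULL, checker_extra = 100, k = 12,
                            ridge_lambda = 1e-3, width_nm = 100,
                            split_fraction = 0.8, train = smoke_config(),
                            augment_ops = NULL, seed = 1) {
  if (is.null(roi_size)) roi_size <- max(8, round(image_size * 240 / 512))
  cfg <- list(out_dir = out_dir, n_hcq = n_hcq, n_normal = n_normal,
              images_per_subject = images_per_subject,
              image_size = image_size, delta = delta, window = window,
              noise_sd = noise_sd, nuisance_sd = nuisance_sd,
              roi_size = roi_size, checker_extra = checker_extra, k = k,
              ridge_lambda = ridge_lambda, width_nm = width_nm,
              split_fraction = split_fraction, train = train,
              augment_ops = augment_ops, seed = as.integer(seed))
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  stopifnot(
    cfg$n_hcq >= 2, cfg$n_normal >= 2, cfg$images_per_subject >= 1,
    cfg$image_size >= 16, length(cfg$window) == 2,
    cfg$window[1] < cfg$window[2], cfg$delta > -1,
    cfg$noise_sd >= 0, cfg$nuisance_sd >= 0,
    cfg$roi_size >= 4, cfg$roi_size <= cfg$image_size,
    cfg$checker_extra >= 0, cfg$k >= 1, cfg$ridge_lambda >= 0,
    cfg$width_nm > 0, cfg$split_fraction > 0, cfg$split_fraction < 1,
    inherits(cfg$train, "train_config")
  )
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields of [pipeline_config()] plus an optional `train:` block of
#' [train_config()] overrides.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  tr <- do.call(smoke_config, y$train %||% list())
  y$train <- NULL
  do.call(pipeline_config, c(y, list(train = tr)))
}

stage_msg <- function(run_log, stage, what) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, what)
  message(line)
  cat(line, "\n", file = run_log, append = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes synthesis, quality control, calibration, spectral conversion,
#' ROI spectral analysis with band-window selection, band-selected color
#' reproduction, optional training-split augmentation, stratified
#' subject-grouped splitting, classifier training on both image variants
#' (ORI and HSI), evaluation, and report generation. A failing stage aborts
#' with the stage name; artifacts written so far stay in place.
#'
#' @param config A [pipeline_config()].
#' @param resume Skip stages whose artifacts already exist.
#' @return The run directory, invisibly; `report.json` inside it holds the
#'   selected band window, cohort statistics and per-variant metrics.
#' @export
run_pipeline <- function(config, resume = FALSE) {
  cfg <- validate_pipeline_config(config)
  rd <- cfg$out_dir
  for (sub in c("", "images", "hsi", "cubes")) {
    dir.create(file.path(rd, sub), recursive = TRUE, showWarnings = FALSE)
  }
  run_log <- file.path(rd, "run.log")
  jsonlite::write_json(c(cfg[setdiff(names(cfg), "train")],
                         list(train = unclass(cfg$train))),
                       file.path(rd, "config.json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  camera <- make_camera_model()

  # --- stage: cohort --------------------------------------------------------
  cohort_file <- file.path(rd, "cohort.csv")
  if (resume && file.exists(cohort_file)) {
    cohort <- read_cohort_csv(cohort_file)
    stage_msg(run_log, "cohort", "resumed")
  } else {
    cohort <- generate_cohort(cfg$n_hcq, cfg$n_normal, seed = cfg$seed,
                              table1_mode = (cfg$n_hcq == 25 && cfg$n_normal == 66),
                              images_per_subject = cfg$images_per_subject)
    write_cohort_csv(cohort, cohort_file)
    stage_msg(run_log, "cohort", sprintf("%d subjects", nrow(cohort)))
  }

  # --- stage: scenes + render ----------------------------------------------
  lm_file <- file.path(rd, "landmarks.csv")
  manifest_file <- file.path(rd, "images.csv")
  if (resume && file.exists(manifest_file)) {
    manifest <- utils::read.csv(manifest_file, stringsAsFactors = FALSE)
    stage_msg(run_log, "scenes", "resumed")
  } else {
    manifest <- NULL; lms <- NULL
    img_seed <- 0L
    for (si in seq_len(nrow(cohort))) {
      row <- cohort[si, ]
      for (img_id in strsplit(row$image_ids, ";")[[1]]) {
        img_seed <- img_seed + 1L
        p <- scene_params(
          label = row$group, age = row$age, delta = cfg$delta,
          window = cfg$window, noise_sd = cfg$noise_sd,
          nuisance_sd = cfg$nuisance_sd,
          size = c(cfg$image_size, cfg$image_size),
          covariates = list(sex = row$sex, hbp = row$hbp,
                            glaucoma = row$glaucoma, amd = row$amd,
                            dr_stage = row$dr_stage))
        sc <- generate_scene(p, seed = cfg$seed * 10000 + img_seed)
        img <- render(sc, camera)
        fn <- file.path(rd, "images", paste0(img_id, ".png"))
        write_image_png(img, fn)
        jsonlite::write_json(
          list(image_id = img_id, label = row$group, subject = row$subject_id,
               covariates = sc$covariates, seed = sc$seed),
          paste0(fn, ".json"), auto_unbox = TRUE)
        manifest <- rbind(manifest, data.frame(
          image_id = img_id, subject_id = row$subject_id, file = fn,
          label = row$group, stringsAsFactors = FALSE))
        lms <- rbind(lms, data.frame(
          image_id = img_id,
          fovea_row = sc$landmarks$fovea_center[1],
          fovea_col = sc$landmarks$fovea_center[2],
          disc_row = sc$landmarks$disc_center[1],
          disc_col = sc$landmarks$disc_center[2],
          arcade_half_height = sc$landmarks$arcade_half_height))
      }
    }
    write_landmarks_csv(lms, lm_file)
    utils::write.csv(manifest, manifest_file, row.names = FALSE)
    stage_msg(run_log, "scenes", sprintf("%d images rendered", nrow(manifest)))
  }
  landmarks_df <- read_landmarks_csv(lm_file)

  # --- stage: quality control ----------------------------------------------
  qc_file <- file.path(rd, "qc.csv")
  if (resume && file.exists(qc_file)) {
    qc <- utils::read.csv(qc_file, stringsAsFactors = FALSE)
    stage_msg(run_log, "qc", "resumed")
  } else {
    qc <- do.call(rbind, lapply(seq_len(nrow(manifest)), function(i) {
      r <- quality_check(read_image_png(manifest$file[i]))
      data.frame(image_id = manifest$image_id[i], sharpness = r$sharpness,
                 saturated_fraction = r$saturated_fraction,
                 dark_fraction = r$dark_fraction, pass = r$pass)
    }))
    utils::write.csv(qc, qc_file, row.names = FALSE)
    stage_msg(run_log, "qc", sprintf("%d/%d images pass", sum(qc$pass), nrow(qc)))
  }
  manifest <- manifest[manifest$image_id %in% qc$image_id[qc$pass], ]
  if (nrow(manifest) < 4) stop("stage qc: too few images pass quality control")

  # --- stage: calibration ---------------------------------------------------
  checker_file <- file.path(rd, "checker.csv")
  checker <- if (resume && file.exists(checker_file)) {
    stage_msg(run_log, "calibrate", "resumed checker")
    read_checker_csv(checker_file)
  } else {
    ck <- generate_checker(camera, cfg$checker_extra, seed = cfg$seed + 1)
    write_checker_csv(ck, checker_file)
    ck
  }
  calib <- fit_calibration(checker, camera, k = cfg$k,
                           lambda = cfg$ridge_lambda)
  stage_msg(run_log, "calibrate",
            sprintf("train RMSE %.4g", calib$fit_report$train_rmse))

  # --- stage: convert + ROI spectra ----------------------------------------
  spectra_file <- file.path(rd, "roi_spectra.csv")
  if (resume && file.exists(spectra_file)) {
    spec_df <- utils::read.csv(spectra_file, stringsAsFactors = FALSE)
    stage_msg(run_log, "spectra", "resumed")
  } else {
    spec_rows <- list()
    for (i in seq_len(nrow(manifest))) {
      img <- read_image_png(manifest$file[i])
      cube <- rgb_to_cube(img, calib)
      lm <- landmarks_df[landmarks_df$image_id == manifest$image_id[i], ]
      rois <- extract_rois(cube,
                           list(fovea_center = c(lm$fovea_row, lm$fovea_col),
                                disc_center = c(lm$disc_row, lm$disc_col),
                                arcade_half_height = lm$arcade_half_height),
                           size = cfg$roi_size)
      for (loc in names(rois)) {
        ms <- colMeans(matrix(rois[[loc]],
                              ncol = dim(rois[[loc]])[3]))
        spec_rows[[length(spec_rows) + 1L]] <- data.frame(
          image_id = manifest$image_id[i], label = manifest$label[i],
          location = loc, t(ms))
      }
    }
    spec_df <- do.call(rbind, spec_rows)
    names(spec_df)[-(1:3)] <- paste0("nm", camera$grid$nm)
    utils::write.csv(spec_df, spectra_file, row.names = FALSE)
    stage_msg(run_log, "spectra", sprintf("%d ROI spectra", nrow(spec_df)))
  }

  # --- stage: band-window selection ----------------------------------------
  band_cols <- paste0("nm", camera$grid$nm)
  windows <- list()
  diffs <- NULL
  for (loc in .ROI_LOCATIONS) {
    sub <- spec_df[spec_df$location == loc, ]
    gh <- group_mean_spectrum(as.matrix(sub[sub$label == "hcq", band_cols]),
                              "hcq", loc, camera$grid)
    gn <- group_mean_spectrum(as.matrix(sub[sub$label == "normal", band_cols]),
                              "normal", loc, camera$grid)
    windows[[loc]] <- select_band_window(gh, gn, cfg$width_nm, camera$grid)
    diffs <- rbind(diffs, abs(gh$mean - gn$mean))
  }
  overall <- select_band_window(colMeans(diffs), rep(0, camera$grid$count),
                                cfg$width_nm, camera$grid)
  stage_msg(run_log, "band_select",
            sprintf("overall window [%g, %g] nm", overall$lo, overall$hi))

  # --- stage: color reproduction -------------------------------------------
  rcfg <- repro_config(window = c(overall$lo, overall$hi))
  hsi_files <- file.path(rd, "hsi", paste0(manifest$image_id, ".png"))
  if (!(resume && all(file.exists(hsi_files)))) {
    for (i in seq_len(nrow(manifest))) {
      img <- read_image_png(manifest$file[i])
      cube <- rgb_to_cube(img, calib)
      write_image_png(reproduce_color(cube, camera, rcfg), hsi_files[i])
    }
  }
  stage_msg(run_log, "reproduce", sprintf("%d HSI images", length(hsi_files)))

  # --- stage: split + augmentation + training + evaluation ------------------
  sp <- stratified_split(manifest$label, cfg$split_fraction,
                         seed = cfg$seed + 2, group_ids = manifest$subject_id)
  split_df <- data.frame(image_id = manifest$image_id,
                         split = ifelse(seq_len(nrow(manifest)) %in% sp$train,
                                        "train", "test"))
  utils::write.csv(split_df, file.path(rd, "split.csv"), row.names = FALSE)

  metrics <- list()
  for (variant in c("ORI", "HSI")) {
    files <- if (variant == "ORI") manifest$file else hsi_files
    mdf <- data.frame(image_id = manifest$image_id, file = files,
                      label = manifest$label, split = split_df$split,
                      stringsAsFactors = FALSE)
    train_df <- mdf[mdf$split == "train", ]
    if (!is.null(cfg$augment_ops)) {
      aug <- build_dataset(train_df, cfg$augment_ops, seed = cfg$seed + 3,
                           out_dir = file.path(rd, paste0("aug_", variant)))
      train_df <- aug[aug$split == "train", c("file", "label")]
      train_df$label <- as.character(train_df$label)
    }
    model <- train_classifier(cfg$train, train_df)
    rep <- evaluate_classifier(model, mdf[mdf$split == "test", ],
                               dataset_variant = variant)
    metrics[[variant]] <- rep
    stage_msg(run_log, "classify",
              sprintf("%s test accuracy %.3f", variant, rep$accuracy))
  }

  # --- stage: report --------------------------------------------------------
  cs <- cohort_stats(cohort)
  report <- list(
    seed = cfg$seed,
    n_images = nrow(manifest),
    reproduction_window = c(overall$lo, overall$hi),
    windows_by_location = lapply(windows, function(w)
      list(lo = w$lo, hi = w$hi, score = w$score)),
    calibration_train_rmse = calib$fit_report$train_rmse,
    cohort_p_values = lapply(cs[names(cs) != "pooled_age_mean"],
                             function(s) s$p_value),
    pooled_age_mean = cs$pooled_age_mean,
    split_counts = as.data.frame(sp$counts),
    metrics = lapply(metrics, function(m)
      list(accuracy = m$accuracy, precision = m$precision,
           recall = m$recall, specificity = m$specificity, f1 = m$f1,
           confusion = m$confusion))
  )
  jsonlite::write_json(report, file.path(rd, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  stage_msg(run_log, "report", "report.json written")
  invisible(rd)
}
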