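# Synthetic case-control cohort mirroring the published covariate table:
# 25 HCQ cases vs 66 normals with fixed marginal counts for sex, high blood
# pressure, glaucoma, AMD and diabetic-retinopathy stage, and group-specific
# normal age distributions.

# reference marginal counts (cases first, then controls)
.TABLE1 <- list(
  n        = c(hcq = 25, normal = 66),
  age_mean = c(hcq = 75.24, normal = 75.83),
  age_sd   = c(hcq = 8.41, normal = 7.52),
  sex      = list(hcq = c(female = 22, male = 3),
                  normal = c(female = 45, male = 21)),
  hbp      = list(hcq = c(pos = 17, neg = 8),
                  normal = c(pos = 59, neg = 7)),
  glaucoma = list(hcq = c(pos = 6, neg = 19),
                  normal = c(pos = 12, neg = 54)),
  amd      = list(hcq = c(pos = 17, neg = 8),
                  normal = c(pos = 49, neg = 17)),
  dr_stage = list(hcq = c(normal = 6, BDR = 6, PDR = 4, PPDR = 9),
                  normal = c(normal = 21, BDR = 11, PDR = 18, PPDR = 16))
)

#' Reference cohort marginal counts
#'
#' The fixed case-control covariate counts and age summaries the default
#' cohort generator reproduces (25 HCQ cases, 66 normals).
#'
#' @return A named list of counts and age summaries per group.
#' @export
cohort_reference_counts <- function() .TABLE1

# assign a categorical covariate: exact counts (shuffled) or proportional draws
.assign_cat <- function(counts, n, exact) {
  levels <- names(counts)
  if (exact) {
    sample(rep(levels, times = counts))
  } else {
    sample(levels, n, replace = TRUE, prob = counts / sum(counts))
  }
}

#' Generate a synthetic study cohort
#'
#' Ages are drawn from group-specific normal distributions (cases: mean 75.24,
#' sd 8.41; controls: mean 75.83, sd 7.52). Categorical covariates are drawn
#' to match the reference proportions; with `table1_mode = TRUE` (requires the
#' default sizes 25 and 66) the categorical counts match the reference table
#' cell for cell.
#'
#' @param n_hcq,n_normal Group sizes (>= 1).
#' @param seed Integer RNG seed.
#' @param table1_mode Logical; reproduce the reference categorical counts
#'   exactly. Only valid with `n_hcq = 25`, `n_normal = 66`.
#' @param images_per_subject Number of image ids attached per subject.
#' @return A `cohort_table` data frame with columns `subject_id`, `group`,
#'   `age`, `sex`, `hbp`, `glaucoma`, `amd`, `dr_stage`, `image_ids`
#'   (semicolon-separated).
#' @examples
#' co <- generate_cohort(25, 66, seed = 1, table1_mode = TRUE)
#' table(co$group, co$sex)
#' @export
generate_cohort <- function(n_hcq = 25, n_normal = 66, seed = 1,
                            table1_mode = FALSE, images_per_subject = 1) {
  stopifnot(n_hcq >= 1, n_normal >= 1, images_per_subject >= 1)
  ref <- .TABLE1
  if (table1_mode && !(n_hcq == ref$n["hcq"] && n_normal == ref$n["normal"])) {
    stop("table1_mode requires the default group sizes 25 (hcq) and 66 (normal)")
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  rows <- lapply(c("hcq", "normal"), function(g) {
    n <- if (g == "hcq") n_hcq else n_normal
    data.frame(
      group = g,
      age = round(stats::rnorm(n, ref$age_mean[g], ref$age_sd[g]), 1),
      sex = .assign_cat(ref$sex[[g]], n, table1_mode),
      hbp = .assign_cat(ref$hbp[[g]], n, table1_mode),
      glaucoma = .assign_cat(ref$glaucoma[[g]], n, table1_mode),
      amd = .assign_cat(ref$amd[[g]], n, table1_mode),
      dr_stage = .assign_cat(ref$dr_stage[[g]], n, table1_mode),
      stringsAsFactors = FALSE
    )
  })
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  df <- do.call(rbind, rows)
  df$subject_id <- sprintf("S%03d", seq_len(nrow(df)))
  df$image_ids <- vapply(df$subject_id, function(sid)
    paste(sprintf("%s_img%d", sid, seq_len(images_per_subject)), collapse = ";"),
    character(1))
  df <- df[, c("subject_id", "group", "age", "sex", "hbp", "glaucoma",
               "amd", "dr_stage", "image_ids")]
  rownames(df) <- NULL
  class(df) <- c("cohort_table", "data.frame")
  df
}
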