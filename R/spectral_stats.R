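# Group spectral comparison with contiguous band-window selection, and the
# case-control summary statistics (two-sample t from summaries, 2x2
# chi-square with continuity correction, RxC chi-square, one-way ANOVA from
# summaries, pooled means).

new_stat_result <- function(test, statistic, df, p_value, effect_size = NA,
                            ci_low = NA, ci_high = NA, note = NULL) {
  structure(
    list(test = test, statistic = unname(statistic), df = unname(df),
         p_value = unname(p_value), effect_size = unname(effect_size),
         ci_low = unname(ci_low), ci_high = unname(ci_high), note = note),
    class = "stat_result"
  )
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: statistic = %.4g, df = %s, p = %.4g\n",
              x$test, x$statistic, paste(signif(x$df, 4), collapse = ","),
              x$p_value))
  invisible(x)
}

#' Pointwise mean and sd spectrum of a group
#'
#' @param spectra An `N x B` matrix of spectra (rows: members), or a list of
#'   such vectors/ROI mean spectra, all on a common grid.
#' @param group,location Labels carried through for reporting.
#' @param grid The [wavelength_grid()] the spectra live on.
#' @return A `group_spectrum`: list with `mean`, `sd` (denominator `n - 1`,
#'   zero when `n = 1`), `n`, `group`, `location`.
#' @export
group_mean_spectrum <- function(spectra, group = NA, location = NA,
                                grid = wavelength_grid()) {
  if (is.list(spectra)) {
    lens <- lengths(spectra)
    if (length(unique(lens)) != 1) stop("spectra are on mixed grids")
    spectra <- do.call(rbind, spectra)
  }
  if (is.null(dim(spectra))) spectra <- matrix(spectra, nrow = 1)
  if (ncol(spectra) != grid$count) {
    stop(sprintf("spectra have %d bands but the grid has %d",
                 ncol(spectra), grid$count))
  }
  n <- nrow(spectra)
  if (n < 1) stop("need at least one member")
  m <- colMeans(spectra)
  s <- if (n == 1) rep(0, ncol(spectra)) else apply(spectra, 2, stats::sd)
  structure(list(mean = m, sd = s, n = n, group = group,
                 location = location, grid = grid),
            class = "group_spectrum")
}

#' Select the band window maximizing the mean absolute group difference
#'
#' Scans every contiguous window of the given width on the grid and returns
#' the one maximizing `mean(|meanA - meanB|)` inside the window; ties break
#' toward the shortest wavelength.
#'
#' @param meanA,meanB Mean spectra (vectors on the grid) or `group_spectrum`
#'   objects.
#' @param width_nm Window width in nm (multiple of the grid step).
#' @param grid The [wavelength_grid()].
#' @return A `band_window`: list with `lo`, `hi` (nm) and `score`.
#' @export
select_band_window <- function(meanA, meanB, width_nm = 100,
                               grid = wavelength_grid()) {
  if (inherits(meanA, "group_spectrum")) meanA <- meanA$mean
  if (inherits(meanB, "group_spectrum")) meanB <- meanB$mean
  stopifnot(length(meanA) == grid$count, length(meanB) == grid$count)
  if (width_nm > grid$stop - grid$start) {
    stop("window width exceeds the grid span")
  }
  if (abs(width_nm / grid$step - round(width_nm / grid$step)) > 1e-9) {
    stop("window width must be a multiple of the grid step")
  }
  w <- round(width_nm / grid$step) + 1          # bands per window (inclusive)
  d <- abs(meanA - meanB)
  cs <- cumsum(c(0, d))
  scores <- (cs[(w + 1):(grid$count + 1)] - cs[1:(grid$count - w + 1)]) / w
  i <- which.max(scores)                        # which.max takes the first max
  structure(list(lo = grid$nm[i], hi = grid$nm[i + w - 1],
                 score = scores[i]),
            class = "band_window")
}

#' @export
print.band_window <- function(x, ...) {
  cat(sprintf("<band_window> [%g, %g] nm, score = %.4g\n", x$lo, x$hi, x$score))
  invisible(x)
}

#' Two-sample t-test from group summaries
#'
#' Pooled-variance unpaired two-tailed t-test computed from means, standard
#' deviations and sizes. Effect size is Cohen's d (mean difference over the
#' pooled sd); the CI is on the mean difference.
#'
#' @param m1,s1,n1 Mean, sd, size of group 1.
#' @param m2,s2,n2 Mean, sd, size of group 2.
#' @param pooled Use the pooled-variance statistic (default). `FALSE` gives
#'   the Welch form.
#' @param conf_level Confidence level for the mean-difference CI.
#' @return A `stat_result`.
#' @examples
#' t_test_from_summary(75.24, 8.41, 25, 75.83, 7.52, 66)$p_value # ~0.75
#' @export
t_test_from_summary <- function(m1, s1, n1, m2, s2, n2, pooled = TRUE,
                                conf_level = 0.95) {
  stopifnot(n1 >= 2, n2 >= 2, s1 >= 0, s2 >= 0)
  diff <- m1 - m2
  if (pooled) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    d_eff <- if (sp2 > 0) diff / sqrt(sp2) else NA
  } else {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    d_eff <- diff / sqrt((s1^2 + s2^2) / 2)
  }
  if (se == 0) {
    if (diff == 0) {
      return(new_stat_result("t_test", 0, df, 1, 0, 0, 0,
                             note = "zero variance, equal means"))
    }
    stop("zero pooled variance with unequal means")
  }
  tstat <- diff / se
  p <- 2 * stats::pt(-abs(tstat), df)
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df)
  new_stat_result("t_test", tstat, df, p, d_eff,
                  diff - tcrit * se, diff + tcrit * se)
}

# odds ratio of a 2x2 table (cross-product)
odds_ratio <- function(tb) (tb[1, 1] * tb[2, 2]) / (tb[1, 2] * tb[2, 1])

#' Chi-square test of association for a 2x2 table
#'
#' Pearson chi-square with Yates continuity correction by default (df = 1,
#' two-sided). The effect size reported is the odds ratio with a Wald
#' log-odds CI.
#'
#' @param table 2x2 matrix of nonnegative integer counts (rows: groups).
#' @param continuity_correction Apply the Yates correction (default `TRUE`).
#' @return A `stat_result`.
#' @examples
#' chi2_2x2(matrix(c(22, 3, 45, 21), 2, byrow = TRUE))$p_value # ~0.10
#' @export
chi2_2x2 <- function(table, continuity_correction = TRUE) {
  tb <- as.matrix(table)
  stopifnot(identical(dim(tb), c(2L, 2L)), all(tb >= 0))
  if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) {
    stop("zero marginal total; the test is undefined")
  }
  ht <- suppressWarnings(stats::chisq.test(tb, correct = continuity_correction))
  or <- odds_ratio(tb)
  ci <- if (all(tb > 0)) {
    se <- sqrt(sum(1 / tb))
    exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se)
  } else c(NA, NA)
  new_stat_result("chi2_2x2", ht$statistic, ht$parameter, ht$p.value,
                  or, ci[1], ci[2])
}

#' Pearson chi-square test for an R x C table
#'
#' No continuity correction; df = (R-1)(C-1). Effect size is Cramer's V.
#'
#' @param table R x C matrix of nonnegative integer counts.
#' @return A `stat_result`.
#' @examples
#' chi2_rxc(matrix(c(6, 6, 4, 9, 21, 11, 18, 16), 2, byrow = TRUE))$p_value # ~0.43
#' @export
chi2_rxc <- function(table) {
  tb <- as.matrix(table)
  stopifnot(all(tb >= 0), nrow(tb) >= 2, ncol(tb) >= 2)
  if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) {
    stop("zero marginal total; the test is undefined")
  }
  ht <- suppressWarnings(stats::chisq.test(tb, correct = FALSE))
  v <- sqrt(unname(ht$statistic) / (sum(tb) * (min(dim(tb)) - 1)))
  new_stat_result("chi2_rxc", ht$statistic, ht$parameter, ht$p.value, v)
}

#' One-way ANOVA from group summaries
#'
#' Between/within mean squares computed from `(mean, sd, n)` triplets.
#' Effect size is eta-squared (between SS over total SS).
#'
#' @param groups List of numeric triplets `c(mean, sd, n)`.
#' @return A `stat_result` with `df = c(k - 1, N - k)`.
#' @export
anova_from_summary <- function(groups) {
  stopifnot(length(groups) >= 2)
  m <- vapply(groups, function(g) g[1], numeric(1))
  s <- vapply(groups, function(g) g[2], numeric(1))
  n <- vapply(groups, function(g) g[3], numeric(1))
  stopifnot(all(n >= 2), all(s >= 0))
  k <- length(groups); N <- sum(n)
  gm <- sum(n * m) / N
  ssb <- sum(n * (m - gm)^2)
  ssw <- sum((n - 1) * s^2)
  df <- c(k - 1, N - k)
  if (ssw == 0) {
    if (ssb == 0) return(new_stat_result("anova", 0, df, 1, 0))
    warning("zero within-group variance with unequal means; reporting p = 0")
    return(new_stat_result("anova", Inf, df, 0, 1))
  }
  fstat <- (ssb / df[1]) / (ssw / df[2])
  p <- stats::pf(fstat, df[1], df[2], lower.tail = FALSE)
  new_stat_result("anova", fstat, df, p, ssb / (ssb + ssw))
}

#' Size-weighted pooled mean
#'
#' @param groups List of `c(mean, n)` pairs.
#' @return The weighted mean.
#' @examples
#' pooled_mean(list(c(75.24, 25), c(75.83, 66))) # 75.67
#' @export
pooled_mean <- function(groups) {
  m <- vapply(groups, function(g) g[1], numeric(1))
  n <- vapply(groups, function(g) g[2], numeric(1))
  stopifnot(all(n >= 1))
  sum(m * n) / sum(n)
}

#' Case-control covariate statistics for a cohort table
#'
#' Reproduces the standard case-control summary: a pooled two-sample t-test
#' on age, Yates-corrected 2x2 chi-square tests for sex, high blood
#' pressure, glaucoma and AMD, and an uncorrected 2x4 chi-square for
#' diabetic-retinopathy stage.
#'
#' @param cohort A `cohort_table` (see [generate_cohort()]), or any data
#'   frame with columns `group`, `age`, `sex`, `hbp`, `glaucoma`, `amd`,
#'   `dr_stage`.
#' @return Named list of `stat_result` objects (`age`, `sex`, `hbp`,
#'   `glaucoma`, `amd`, `dr_stage`) plus `pooled_age_mean`.
#' @export
cohort_stats <- function(cohort) {
  g <- split(cohort, cohort$group)
  stopifnot(all(c("hcq", "normal") %in% names(g)))
  h <- g$hcq; n <- g$normal
  tab2 <- function(col, pos_level) {
    rbind(hcq = c(sum(h[[col]] == pos_level), sum(h[[col]] != pos_level)),
          normal = c(sum(n[[col]] == pos_level), sum(n[[col]] != pos_level)))
  }
  dr_levels <- c("normal", "BDR", "PDR", "PPDR")
  dr_tab <- rbind(hcq = table(factor(h$dr_stage, dr_levels)),
                  normal = table(factor(n$dr_stage, dr_levels)))
  dr_tab <- dr_tab[, colSums(dr_tab) > 0, drop = FALSE]
  # small cohorts can produce degenerate margins; report those as untestable
  safe <- function(expr) tryCatch(expr, error = function(e)
    new_stat_result("untestable", NA, NA, NA, note = conditionMessage(e)))
  list(
    age = t_test_from_summary(mean(h$age), stats::sd(h$age), nrow(h),
                              mean(n$age), stats::sd(n$age), nrow(n)),
    sex = safe(chi2_2x2(tab2("sex", "female"))),
    hbp = safe(chi2_2x2(tab2("hbp", "pos"))),
    glaucoma = safe(chi2_2x2(tab2("glaucoma", "pos"))),
    amd = safe(chi2_2x2(tab2("amd", "pos"))),
    dr_stage = safe(chi2_rxc(dr_tab)),
    pooled_age_mean = pooled_mean(list(c(mean(h$age), nrow(h)),
                                       c(mean(n$age), nrow(n))))
  )
}
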