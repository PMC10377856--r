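test_that("group mean spectra match a per-band recomputation", {
  g <- wavelength_grid()
  one <- matrix(runif(401), 1)
  gs <- group_mean_spectrum(one, "hcq", "F")
  expect_equal(gs$mean, as.numeric(one))
  expect_equal(gs$sd, rep(0, 401))
  two <- rbind(rep(0.2, 401), rep(0.4, 401))
  expect_equal(group_mean_spectrum(two)$mean, rep(0.3, 401))
  set.seed(21)
  m <- matrix(runif(5 * 401), 5)
  gs <- group_mean_spectrum(m)
  expect_equal(gs$mean, apply(m, 2, mean))
  expect_equal(gs$sd, apply(m, 2, sd))
  expect_error(group_mean_spectrum(list(runif(401), runif(400))), "mixed grids")
})

test_that("band-window selection equals exhaustive search and honors ties", {
  g <- wavelength_grid()
  # boxcar difference on [500, 600] is recovered exactly
  a <- rep(0.5, 401); b <- a
  b[g$nm >= 500 & g$nm <= 600] <- 0.55
  w <- select_band_window(a, b, 100)
  expect_equal(c(w$lo, w$hi), c(500, 600))
  # identical means: zero score, tie broken to the shortest wavelength
  w0 <- select_band_window(a, a, 100)
  expect_equal(c(w0$lo, w0$hi, w0$score), c(380, 480, 0))
  # brute-force oracle on random spectra
  set.seed(31)
  for (rep in 1:5) {
    x <- cumsum(rnorm(401, 0, 0.01)); y <- cumsum(rnorm(401, 0, 0.01))
    width <- sample(c(50, 100, 150), 1)
    w <- select_band_window(x, y, width)
    d <- abs(x - y)
    nb <- width + 1
    scores <- vapply(seq_len(401 - nb + 1), function(i)
      mean(d[i:(i + nb - 1)]), numeric(1))
    expect_equal(w$score, max(scores), tolerance = 1e-12)
    expect_equal(w$lo, g$nm[which.max(scores)])
  }
  expect_error(select_band_window(a, b, 500), "exceeds")
})

test_that("summary t-test reproduces the case-control age comparison", {
  r <- t_test_from_summary(75.24, 8.41, 25, 75.83, 7.52, 66)
  expect_equal(round(r$p_value, 2), 0.75)
  expect_lt(r$ci_low, -0.59); expect_gt(r$ci_high, -0.59)
  same <- t_test_from_summary(5, 1, 10, 5, 1, 10)
  expect_equal(same$statistic, 0); expect_equal(same$p_value, 1)
  degenerate <- t_test_from_summary(3, 0, 5, 3, 0, 5)
  expect_equal(degenerate$p_value, 1)
  expect_error(t_test_from_summary(3, 0, 5, 4, 0, 5), "zero pooled variance")
})

test_that("summary t-test agrees with t.test and a permutation oracle on raw data", {
  set.seed(41)
  x <- round(rnorm(9, 70, 6), 1); y <- round(rnorm(12, 74, 6), 1)
  ours <- t_test_from_summary(mean(x), sd(x), length(x),
                              mean(y), sd(y), length(y))
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(c(ours$ci_low, ours$ci_high), as.numeric(ref$conf.int),
               tolerance = 1e-10)
  # permutation distribution of |mean difference|
  pool <- c(x, y); nx <- length(x)
  obs <- abs(mean(x) - mean(y))
  B <- 1e5
  perm <- replicate(B, {
    idx <- sample.int(length(pool), nx)
    abs(mean(pool[idx]) - mean(pool[-idx]))
  })
  p_perm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(p_perm - ours$p_value), 0.02)
})

test_that("2x2 chi-square with continuity correction reproduces the cohort table", {
  expect_equal(round(chi2_2x2(rbind(c(22, 3), c(45, 21)))$p_value, 2), 0.10)
  expect_equal(round(chi2_2x2(rbind(c(17, 8), c(59, 7)))$p_value, 2), 0.03)
  expect_equal(round(chi2_2x2(rbind(c(6, 19), c(12, 54)))$p_value, 2), 0.74)
  expect_equal(round(chi2_2x2(rbind(c(17, 8), c(49, 17)))$p_value, 2), 0.74)
  even <- chi2_2x2(rbind(c(10, 10), c(10, 10)))
  expect_equal(even$statistic, 0, ignore_attr = TRUE)
  expect_equal(even$p_value, 1)
  expect_error(chi2_2x2(rbind(c(0, 0), c(5, 5))), "marginal")
})

test_that("removing the continuity correction never increases the 2x2 p-value", {
  set.seed(51)
  for (i in 1:20) {
    tb <- matrix(rpois(4, 15) + 1, 2)
    expect_lte(chi2_2x2(tb, continuity_correction = FALSE)$p_value,
               chi2_2x2(tb, continuity_correction = TRUE)$p_value + 1e-12)
  }
})

test_that("the 2x2 test holds its size under a multinomial null", {
  # n = 91 subjects, margins from the reference cohort (group 25/66,
  # covariate 67/24 as for sex); Yates-corrected Pearson statistic
  set.seed(61)
  n <- 91
  pr <- outer(c(25, 66) / 91, c(67, 24) / 91)
  B <- 1e4
  cells <- rmultinom(B, n, as.numeric(pr))
  # vectorized Yates statistic as an independent oracle for the rejection rate
  a <- cells[1, ]; b <- cells[2, ]; c2 <- cells[3, ]; d <- cells[4, ]
  N <- a + b + c2 + d
  stat <- N * pmax(abs(a * d - b * c2) - N / 2, 0)^2 /
    ((a + b) * (c2 + d) * (a + c2) * (b + d))
  ok <- (a + b) > 0 & (c2 + d) > 0 & (a + c2) > 0 & (b + d) > 0
  rej <- mean(stats::pchisq(stat[ok], 1, lower.tail = FALSE) < 0.05)
  expect_lte(rej, 0.06)
})

test_that("RxC chi-square matches the (O-E)^2/E oracle and the cohort table", {
  r <- chi2_rxc(rbind(c(6, 6, 4, 9), c(21, 11, 18, 16)))
  expect_equal(round(r$p_value, 2), 0.43)
  expect_equal(r$df, c(3), ignore_attr = TRUE)
  prop <- rbind(c(10, 20, 30), c(20, 40, 60))
  expect_equal(chi2_rxc(prop)$statistic, 0, ignore_attr = TRUE)
  expect_equal(chi2_rxc(prop)$p_value, 1)
  set.seed(71)
  for (i in 1:5) {
    tb <- matrix(rpois(8, 12) + 1, 2)
    r <- chi2_rxc(tb)
    E <- outer(rowSums(tb), colSums(tb)) / sum(tb)
    expect_equal(r$statistic, sum((tb - E)^2 / E), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("summary ANOVA reproduces the age-decade comparison and raw aov", {
  r <- anova_from_summary(list(c(62.90, 3.57, 15), c(74.97, 2.27, 47),
                               c(82.50, 1.92, 29)))
  expect_lt(r$p_value, 1e-4)
  expect_equal(r$df, c(2, 88), ignore_attr = TRUE)
  flat <- anova_from_summary(list(c(5, 1, 10), c(5, 2, 12), c(5, 1.5, 8)))
  expect_equal(flat$statistic, 0); expect_equal(flat$p_value, 1)
  # raw-data oracle: construct samples whose summaries equal the inputs
  mk <- function(m, s, n) { z <- scale(rnorm(n)); as.numeric(m + s * z) }
  set.seed(81)
  gs <- list(mk(10, 2, 8), mk(12, 3, 10), mk(9, 2.5, 7))
  summ <- lapply(gs, function(v) c(mean(v), sd(v), length(v)))
  ours <- anova_from_summary(summ)
  df <- data.frame(y = unlist(gs),
                   g = factor(rep(seq_along(gs), lengths(gs))))
  ref <- summary(aov(y ~ g, df))[[1]]
  expect_equal(ours$statistic, ref[["F value"]][1], tolerance = 1e-8)
  expect_equal(ours$p_value, ref[["Pr(>F)"]][1], tolerance = 1e-8)
})

test_that("pooled mean weights groups by size", {
  expect_equal(round(pooled_mean(list(c(75.24, 25), c(75.83, 66))), 2), 75.67)
  expect_equal(pooled_mean(list(c(4.2, 17))), 4.2)
  expect_equal(pooled_mean(list(c(2, 5), c(6, 5))), 4)
})

test_that("cohort_stats reproduces the full covariate table on the reference cohort", {
  co <- generate_cohort(25, 66, seed = 13, table1_mode = TRUE)
  cs <- cohort_stats(co)
  expect_equal(round(cs$sex$p_value, 2), 0.10)
  expect_equal(round(cs$hbp$p_value, 2), 0.03)
  expect_equal(round(cs$glaucoma$p_value, 2), 0.74)
  expect_equal(round(cs$amd$p_value, 2), 0.74)
  expect_equal(round(cs$dr_stage$p_value, 2), 0.43)
  expect_true(cs$age$p_value > 0 && cs$age$p_value <= 1)
})
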