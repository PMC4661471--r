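test_that("chi-square homogeneity handles canonical and degenerate tables", {
  expect_equal(chi_square_homogeneity(c(50, 50), c(50, 50)),
               list(chi2 = 0, df = 1L, p = 1, k = 2L))
  # pooled proportion 0.5, hand evaluation gives 128 on 2 df
  r <- chi_square_homogeneity(c(10, 50, 90), c(90, 50, 10))
  expect_equal(r$chi2, 128)
  expect_equal(r$df, 2L)
  expect_lt(r$p, 1e-27)
  # degenerate column: no observable variation in proportion
  expect_equal(chi_square_homogeneity(c(0, 0, 0), c(100, 100, 100))$chi2, 0)
  expect_equal(chi_square_homogeneity(c(0, 0, 0), c(100, 100, 100))$p, 1)
  # zero-total individuals are excluded, reducing k
  r2 <- chi_square_homogeneity(c(10, 0, 90), c(90, 0, 10))
  expect_equal(r2$k, 2L)
  expect_equal(r2$df, 1L)
  # untestable sentinel below 2 usable individuals
  expect_true(is.na(chi_square_homogeneity(c(5, 0), c(5, 0))$p))
  expect_error(chi_square_homogeneity(1:3, 1:2), "equal length")
})

test_that("chi-square agrees with the generic contingency implementation", {
  set.seed(17)
  worst <- 0
  for (i in 1:1000) {
    k <- sample(2:12, 1)
    m <- rpois(k, sample(c(2, 10, 50), 1)) + 1L
    u <- rpois(k, sample(c(2, 10, 50), 1)) + 1L
    mine <- chi_square_homogeneity(m, u)
    ref <- suppressWarnings(stats::chisq.test(cbind(m, u), correct = FALSE))
    worst <- max(worst, abs(mine$chi2 - unname(ref$statistic)) /
                   max(unname(ref$statistic), 1e-12))
    expect_equal(mine$df, unname(ref$parameter))
  }
  expect_lt(worst, 1e-9)
})

test_that("the statistic is invariant to relabelling and column swap, and grows with counts", {
  set.seed(23)
  for (i in 1:50) {
    k <- sample(3:11, 1)
    m <- rpois(k, 20) + 1L; u <- rpois(k, 30) + 1L
    base <- chi_square_homogeneity(m, u)$chi2
    perm <- sample(k)
    expect_equal(chi_square_homogeneity(m[perm], u[perm])$chi2, base)
    expect_equal(chi_square_homogeneity(u, m)$chi2, base)
    if (base > 0)
      expect_gt(chi_square_homogeneity(3L * m, 3L * u)$chi2, base)
  }
})

test_that("Bonferroni threshold is alpha over the family size", {
  expect_equal(bonferroni_threshold(0.001, 64934), 0.001 / 64934)
  expect_equal(round(bonferroni_threshold(0.001, 64934), 10), 1.54e-8)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 41464), 0.05 / 41464)
  expect_lt(abs(bonferroni_threshold(0.05, 41464) - 1.206e-6), 1e-9)
  expect_error(bonferroni_threshold(0.001, 0), "m_tests")
})

test_that("dispersion metrics implement the binomial-scaled CV and logit", {
  d <- dispersion_metrics(rep(40, 5))
  expect_equal(d$sd, 0)
  expect_true(is.na(d$log_sd))
  expect_equal(d$mod_cv, 0)
  # mean 50, sd 5, k = 11
  x <- c(rep(45, 5), rep(55, 5), 50)
  d2 <- dispersion_metrics(x)
  expect_equal(d2$mean_pct, 50)
  expect_equal(d2$sd, 5)
  expect_equal(d2$mod_cv, 5 / sqrt(50 * 50 / 11), tolerance = 1e-12)
  expect_equal(round(d2$mod_cv, 4), 0.3317)
  expect_equal(d2$logit_mean, 0)
  # sentinels at the scale boundaries
  d3 <- dispersion_metrics(c(0, 0, 0))
  expect_true(is.na(d3$mod_cv) && is.na(d3$logit_mean))
})

test_that("iVMF calling is inclusive at the cutoff and splits allosomes", {
  res <- data.frame(fragment_id = c("a", "b", "c"),
                    chrom = c("chr1", "chrX", "chr2"),
                    p = c(1e-9, 1e-10, 1e-9), autosomal = c(TRUE, FALSE, TRUE))
  got <- call_ivmfs(res, cutoff = 1e-9)
  expect_setequal(got$fragment_id, c("a", "b", "c"))  # p == cutoff is called
  got2 <- call_ivmfs(res, cutoff = 1e-9, autosomal_only = TRUE)
  expect_setequal(got2$fragment_id, c("a", "c"))
})

test_that("ivmf_test matches per-fragment chi-square and reports diagnostics", {
  w <- small_world()
  fit <- w$fit
  r <- fit$results
  # spot-check several fragments against the scalar implementation
  idx <- match(r$fragment_id, w$cohort$fragments$fragment_id)
  set.seed(2)
  for (i in sample(nrow(r), 25)) {
    m <- w$cohort$M[idx[i], ]; u <- w$cohort$U[idx[i], ]
    q <- w$cohort$qualified[idx[i], ]
    ref <- chi_square_homogeneity(m[q], u[q])
    expect_equal(r$chi2[i], ref$chi2, tolerance = 1e-12)
    expect_equal(r$p[i], ref$p, tolerance = 1e-12)
    expect_equal(r$k[i], ref$k)
  }
  expect_equal(fit$cutoff, fit$alpha / fit$m_tests)
  expect_true(all(r$df == r$k - 1L))
  expect_true(all(r$p >= 0 & r$p <= 1, na.rm = TRUE))
  s <- summary(fit)
  expect_equal(s$n_ivmf, sum(r$is_ivmf, na.rm = TRUE))
  # iVMFs are more dispersed than the non-variable background
  expect_gt(s$median_sd_ivmf, s$median_sd_nonvar)
  expect_output(print(fit), "Bonferroni")
  expect_output(print(s), "iVMFs")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit, which = "log_sd"))
})

test_that("two-group ANOVA matches the hand-computed example and flags filters", {
  a <- group_anova(c(10, 20, 30, 40, 50, 60), rep(c("g1", "g2"), each = 3))
  expect_equal(a$F, 13.5)
  expect_equal(a$df2, 4)
  expect_equal(a$mean_diff, 30)
  expect_equal(a$p, 1 - pf(13.5, 1, 4))
  # identical group means with nonzero within-variance
  b <- group_anova(c(10, 30, 10, 30), c("g1", "g2", "g2", "g1"))
  expect_equal(b$F, 0)
  # untestable sentinel when a group has < 2 members
  c1 <- group_anova(c(10, 20, 30), c("g1", "g1", "g2"))
  expect_true(is.na(c1$F) && is.na(c1$p))
  expect_equal(c1$mean_diff, 15)
  expect_error(group_anova(1:3, c("a", "b", "c")), "two groups")
})

test_that("cohort group comparison applies the mean-difference filter strictly", {
  cfg <- sim_config(seed = 19, n_individuals = 11, n_chromosomes = 1,
                    chrom_length = 80000L,
                    sexes = c(rep("M", 5), rep("F", 6)))
  gs <- simulate_genome(cfg)
  ms <- simulate_methylome(gs)
  tabs <- lapply(ms$calls, aggregate_fragment_methylation,
                 fragments = ms$fragments)
  ch <- assemble_cohort(tabs, ms$fragments, min_individuals = 9)
  cmp <- group_anova_cohort(ch, setNames(cfg$sexes, ms$individuals))
  expect_true(all(cmp$mean_diff[cmp$passes_mean_diff] >= 20))
  expect_false(any(cmp$passes_mean_diff & cmp$mean_diff < 20))
  # sex-differential chrX fragments dominate the >= 20-point list
  hits <- cmp$fragment_id[cmp$passes_mean_diff]
  tr <- ms$truth[match(hits, ms$truth$fragment_id), ]
  expect_gt(mean(tr$is_sex_diff), 0.9)
  x_share <- 100 * mean(cmp$chrom[cmp$passes_mean_diff] == "chrX")
  expect_gt(x_share, 80)
})

test_that("Bland-Altman limits follow the closed form", {
  r <- bland_altman(c(10, 20, 30), c(10, 20, 30))
  expect_equal(r$bias, 0)
  expect_equal(r$lower, 0)
  expect_equal(r$upper, 0)
  r2 <- bland_altman(c(12, 22, 32), c(10, 20, 30))
  expect_equal(r2$bias, 2)
  expect_equal(c(r2$lower, r2$upper), c(2, 2))
  set.seed(40)
  d <- rnorm(10000, 0, 5.92)
  r3 <- bland_altman(d, rep(0, 10000))
  expect_equal(r3$lower, -1.96 * 5.92, tolerance = 0.03)
  expect_equal(r3$upper, 1.96 * 5.92, tolerance = 0.03)
  expect_error(bland_altman(1, 2), "two complete pairs")
})
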