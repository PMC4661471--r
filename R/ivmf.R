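#' Chi-square homogeneity test of methylation proportions
#'
#' Tests whether the methylation proportion of one fragment is homogeneous
#' across individuals, treating every CpG read observation as an
#' individual Bernoulli outcome.  The k x 2 table has one row per
#' individual (methylated vs unmethylated observation counts); expected
#' cells are `row_total * column_total / grand_total`, the statistic is the
#' usual Pearson sum without continuity correction, and the degrees of
#' freedom are `k - 1`.  Individuals with zero total observations are
#' excluded (reducing k); if either pooled column is empty there is no
#' observable variation in proportion and `(0, k - 1, 1)` is returned.
#'
#' @param m,u Integer vectors of methylated / unmethylated observation
#'   counts per individual.
#' @return List with `chi2`, `df`, `p` and `k` (individuals tested).
#'   `k < 2` after exclusion yields the untestable sentinel
#'   (`chi2 = NA`, `p = NA`).
#' @examples
#' chi_square_homogeneity(c(10, 50, 90), c(90, 50, 10))  # chi2 = 128, df = 2
#' @export
chi_square_homogeneity <- function(m, u) {
  if (length(m) != length(u)) stop("m and u must have equal length")
  keep <- (m + u) > 0
  m <- m[keep]; u <- u[keep]
  k <- length(m)
  if (k < 2L) return(list(chi2 = NA_real_, df = NA_integer_, p = NA_real_, k = k))
  Tm <- sum(m); Tu <- sum(u); G <- Tm + Tu
  if (Tm == 0 || Tu == 0)
    return(list(chi2 = 0, df = k - 1L, p = 1, k = k))
  pp <- Tm / G
  Em <- (m + u) * pp
  Eu <- (m + u) * (1 - pp)
  chi2 <- sum((m - Em)^2 / Em + (u - Eu)^2 / Eu)
  list(chi2 = chi2, df = k - 1L,
       p = pchisq(chi2, k - 1L, lower.tail = FALSE), k = k)
}

#' Bonferroni-adjusted significance cutoff
#'
#' Family-wise error control for fragment-level testing: the per-test
#' cutoff is `alpha / m_tests`, with the family size being the number of
#' analysed fragments in the current run.
#'
#' @param alpha Nominal significance level (default 0.001, a deliberately
#'   stringent base level because read observations of neighbouring CpGs
#'   within a fragment are correlated).
#' @param m_tests Number of tests in the family.
#' @return The adjusted p-value cutoff.
#' @examples
#' bonferroni_threshold(0.001, 64934)  # 1.54e-8
#' @export
bonferroni_threshold <- function(alpha = 0.001, m_tests) {
  if (m_tests < 1L) stop("m_tests must be at least 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  alpha / m_tests
}

#' Dispersion diagnostics for one fragment
#'
#' Summaries of the spread of per-individual methylation percentages: the
#' sample standard deviation, a binomial-scaled (modified) coefficient of
#' variation `sd / sqrt(mean * (100 - mean) / k)` that accounts for the
#' bounded 0-100% scale, their natural logs, and the logit of the mean,
#' `log(mean / (100 - mean))`, which spreads fragments near 0% and 100%.
#' The modified CV and logit are undefined (`NA`) at mean 0 or 100; logs
#' of zero are returned as `NA`.
#'
#' @param pct Numeric vector of per-individual methylation percentages
#'   (`NA` entries dropped).
#' @return List with `k`, `mean_pct`, `sd`, `mod_cv`, `log_sd`, `log_cv`,
#'   `logit_mean`.
#' @export
dispersion_metrics <- function(pct) {
  pct <- pct[!is.na(pct)]
  k <- length(pct)
  if (k < 2L)
    return(list(k = k, mean_pct = if (k) mean(pct) else NA_real_,
                sd = NA_real_, mod_cv = NA_real_, log_sd = NA_real_,
                log_cv = NA_real_, logit_mean = NA_real_))
  m <- mean(pct); s <- sd(pct)
  denom <- sqrt(m * (100 - m) / k)
  mod_cv <- if (m <= 0 || m >= 100) NA_real_ else s / denom
  list(k = k, mean_pct = m, sd = s, mod_cv = mod_cv,
       log_sd = if (s > 0) log(s) else NA_real_,
       log_cv = if (!is.na(mod_cv) && mod_cv > 0) log(mod_cv) else NA_real_,
       logit_mean = if (m <= 0 || m >= 100) NA_real_ else log(m / (100 - m)))
}

#' Call inter-individual variably methylated fragments
#'
#' The statistical core of the package.  For every analysed fragment of a
#' cohort it runs the chi-square homogeneity test across the qualified
#' individuals, computes the dispersion diagnostics, and calls iVMFs at
#' the Bonferroni-adjusted cutoff `alpha / n_analysed` using the inclusive
#' rule `p <= cutoff`.
#'
#' @param cohort A `"meth_cohort"` from [assemble_cohort()] or
#'   [simulate_fragment_counts()].
#' @param alpha Base significance level before Bonferroni correction
#'   (default 0.001).
#' @param allosomes Chromosome names excluded from the autosomal iVMF
#'   subset (default `chrX`, `chrY`).
#' @return An object of class `"ivmf_fit"`: a `results` data.frame
#'   (fragment_id, chrom, start, end, k, chi2, df, p, mean_pct, sd,
#'   mod_cv, log_sd, log_cv, logit_mean, is_ivmf, autosomal), plus
#'   `alpha`, `m_tests`, `cutoff`, `allosomes` and the originating call.
#'   Methods: `print`, `summary`, `plot`, `as.data.frame`.
#' @export
ivmf_test <- function(cohort, alpha = 0.001, allosomes = c("chrX", "chrY")) {
  stopifnot(inherits(cohort, "meth_cohort"))
  idx <- match(cohort$analysed_ids, cohort$fragments$fragment_id)
  if (!length(idx)) stop("cohort has no analysed fragments")
  M <- cohort$M[idx, , drop = FALSE] * 1.0
  U <- cohort$U[idx, , drop = FALSE] * 1.0
  drop <- !cohort$qualified[idx, , drop = FALSE] | (M + U) == 0
  M[drop] <- NA_real_; U[drop] <- NA_real_

  k <- rowSums(!is.na(M))
  Tm <- rowSums(M, na.rm = TRUE); Tu <- rowSums(U, na.rm = TRUE)
  G <- Tm + Tu
  pp <- Tm / G
  Em <- (M + U) * pp
  Eu <- (M + U) * (1 - pp)
  chi2 <- rowSums((M - Em)^2 / Em, na.rm = TRUE) +
    rowSums((U - Eu)^2 / Eu, na.rm = TRUE)
  chi2[Tm == 0 | Tu == 0] <- 0
  df <- k - 1L
  p <- pchisq(chi2, df, lower.tail = FALSE)
  p[Tm == 0 | Tu == 0] <- 1
  untestable <- k < 2L
  chi2[untestable] <- NA_real_; p[untestable] <- NA_real_

  P <- 100 * M / (M + U)
  disp <- t(apply(P, 1L, function(row) {
    d <- dispersion_metrics(row)
    c(d$mean_pct, d$sd, d$mod_cv, d$log_sd, d$log_cv, d$logit_mean)
  }))
  colnames(disp) <- c("mean_pct", "sd", "mod_cv", "log_sd", "log_cv",
                      "logit_mean")

  m_tests <- sum(!untestable)
  cutoff <- bonferroni_threshold(alpha, m_tests)
  fr <- cohort$fragments[idx, , drop = FALSE]
  res <- data.frame(fragment_id = fr$fragment_id, chrom = fr$chrom,
                    start = fr$start, end = fr$end, k = k, chi2 = chi2,
                    df = df, p = p, disp,
                    is_ivmf = !is.na(p) & p <= cutoff,
                    autosomal = !(fr$chrom %in% allosomes),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(results = res, alpha = alpha, m_tests = m_tests,
                 cutoff = cutoff, allosomes = allosomes,
                 n_individuals = length(cohort$individuals),
                 call = match.call()),
            class = "ivmf_fit")
}

#' Extract the iVMF set from a fit
#'
#' @param fit An `"ivmf_fit"`, or a results data.frame with `p` values.
#' @param cutoff Overrides the fit's Bonferroni cutoff.  iVMFs are called
#'   with the inclusive rule `p <= cutoff`.
#' @param autosomal_only Drop allosomal fragments (default FALSE).
#' @return The rows of the results table called as iVMFs.
#' @export
call_ivmfs <- function(fit, cutoff = NULL, autosomal_only = FALSE) {
  res <- if (inherits(fit, "ivmf_fit")) fit$results else fit
  if (is.null(cutoff)) cutoff <- fit$cutoff
  out <- res[!is.na(res$p) & res$p <= cutoff, , drop = FALSE]
  if (autosomal_only && !is.null(out$autosomal))
    out <- out[out$autosomal, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.ivmf_fit <- function(x, ...) {
  r <- x$results
  cat("Inter-individual methylation variability (chi-square homogeneity)\n")
  cat(sprintf("  analysed fragments: %d (cohort of %d individuals)\n",
              x$m_tests, x$n_individuals))
  cat(sprintf("  Bonferroni cutoff: alpha %.3g / %d tests = %.3g\n",
              x$alpha, x$m_tests, x$cutoff))
  n_iv <- sum(r$is_ivmf, na.rm = TRUE)
  cat(sprintf("  iVMFs: %d (%.1f%% of analysed); autosomal iVMFs: %d\n",
              n_iv, 100 * n_iv / x$m_tests,
              sum(r$is_ivmf & r$autosomal, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.ivmf_fit <- function(object, ...) {
  r <- object$results
  iv <- r$is_ivmf %in% TRUE
  out <- list(n_analysed = object$m_tests,
              n_ivmf = sum(iv),
              pct_ivmf = 100 * sum(iv) / object$m_tests,
              n_ivmf_autosomal = sum(iv & r$autosomal),
              cutoff = object$cutoff, alpha = object$alpha,
              median_sd_all = median(r$sd, na.rm = TRUE),
              median_sd_ivmf = median(r$sd[iv], na.rm = TRUE),
              median_sd_nonvar = median(r$sd[!iv], na.rm = TRUE))
  class(out) <- "summary.ivmf_fit"
  out
}

#' @export
print.summary.ivmf_fit <- function(x, ...) {
  cat(sprintf("analysed fragments : %d\n", x$n_analysed))
  cat(sprintf("iVMFs              : %d (%.1f%%), cutoff %.3g (alpha %.3g)\n",
              x$n_ivmf, x$pct_ivmf, x$cutoff, x$alpha))
  cat(sprintf("autosomal iVMFs    : %d\n", x$n_ivmf_autosomal))
  cat(sprintf("median SD          : all %.2f | iVMF %.2f | non-variable %.2f\n",
              x$median_sd_all, x$median_sd_ivmf, x$median_sd_nonvar))
  invisible(x)
}

#' @export
as.data.frame.ivmf_fit <- function(x, ...) x$results

#' Diagnostic plots of methylation variability
#'
#' Scatter of a dispersion measure against mean methylation (or its
#' logit), with iVMFs overlaid: `which = "sd"` (SD vs mean), `"cv"`
#' (modified CV vs mean), `"log_sd"` and `"log_cv"` (log-dispersion vs
#' logit mean).  The transforms separate variable fragments from the
#' non-variable background much more clearly near 0% and 100% methylation.
#'
#' @param x An `"ivmf_fit"`.
#' @param which One of `"sd"`, `"cv"`, `"log_sd"`, `"log_cv"`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.ivmf_fit <- function(x, which = c("sd", "cv", "log_sd", "log_cv"), ...) {
  which <- match.arg(which)
  r <- x$results
  ax <- switch(which,
               sd = list(r$mean_pct, r$sd, "mean methylation (%)", "SD"),
               cv = list(r$mean_pct, r$mod_cv, "mean methylation (%)",
                         "modified CV"),
               log_sd = list(r$logit_mean, r$log_sd, "logit mean methylation",
                             "log SD"),
               log_cv = list(r$logit_mean, r$log_cv, "logit mean methylation",
                             "log modified CV"))
  plot(ax[[1]], ax[[2]], col = adjustcolor("red3", 0.4), pch = 16, cex = 0.5,
       xlab = ax[[3]], ylab = ax[[4]], ...)
  iv <- r$is_ivmf %in% TRUE
  points(ax[[1]][iv], ax[[2]][iv], col = adjustcolor("blue3", 0.6),
         pch = 16, cex = 0.5)
  legend("topright", c("analysed", "iVMF"), col = c("red3", "blue3"),
         pch = 16, bty = "n")
  invisible(x)
}

#' Cohort and iVMF share summaries
#'
#' The percentage summaries reported alongside an iVMF analysis: the iVMF
#' share of analysed fragments, the iVMF CpG share of analysed CpGs, the
#' iVMF share of the RR genome, and analogous shares for any
#' numerator/denominator pair.
#'
#' @param n_part,n_total Numerator and denominator counts.
#' @return The share as a percentage.
#' @export
share_pct <- function(n_part, n_total) {
  if (any(n_total <= 0)) stop("denominator must be positive")
  100 * n_part / n_total
}

#' @describeIn share_pct Named vector of the standard iVMF shares: of the
#'   analysed fragments, of the RR genome, and of analysed CpG sites.
#' @param n_ivmf,n_analysed,n_rr Fragment counts (iVMFs, analysed set, RR
#'   genome).
#' @param cpgs_ivmf,cpgs_analysed Optional CpG-site counts in iVMFs and in
#'   the analysed set.
#' @export
ivmf_shares <- function(n_ivmf, n_analysed, n_rr = NA,
                        cpgs_ivmf = NA, cpgs_analysed = NA) {
  c(pct_of_analysed = share_pct(n_ivmf, n_analysed),
    pct_of_rr_genome = if (is.na(n_rr)) NA_real_ else share_pct(n_ivmf, n_rr),
    cpg_pct_of_analysed = if (is.na(cpgs_ivmf) || is.na(cpgs_analysed))
      NA_real_ else share_pct(cpgs_ivmf, cpgs_analysed))
}
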