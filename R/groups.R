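#' Two-group ANOVA on fragment methylation
#'
#' Classical one-way analysis of variance between two groups of
#' individuals (e.g. male vs female) on per-individual fragment
#' methylation percentages, plus the absolute difference of the group
#' means.  Fragments are ranked both by Bonferroni-corrected significance
#' and, separately, by a mean-difference filter applied irrespective of
#' the p-value.
#'
#' @param pct Numeric vector of methylation percentages (`NA` dropped
#'   together with its label).
#' @param groups Vector of group labels; exactly two distinct groups.
#' @return List with `group_means`, `mean_diff`, `F`, `df1`, `df2`, `p`.
#'   A group with fewer than 2 non-missing members yields the untestable
#'   sentinel (`F = NA`, `p = NA`) with means still reported.
#' @examples
#' group_anova(c(10, 20, 30, 40, 50, 60), rep(c("M", "F"), each = 3))
#' @export
group_anova <- function(pct, groups) {
  ok <- !is.na(pct) & !is.na(groups)
  pct <- pct[ok]; groups <- as.character(groups[ok])
  lev <- sort(unique(groups))
  if (length(lev) != 2L) stop("exactly two groups are required")
  gm <- vapply(lev, function(g) mean(pct[groups == g]), numeric(1))
  out <- list(group_means = gm, mean_diff = unname(abs(diff(gm))),
              F = NA_real_, df1 = 1L, df2 = length(pct) - 2L, p = NA_real_)
  if (any(table(groups) < 2L)) return(out)
  fit <- oneway.test(pct ~ factor(groups), var.equal = TRUE)
  out$F <- unname(fit$statistic)
  out$df2 <- unname(fit$parameter[2L])
  out$p <- fit$p.value
  out
}

#' Cohort-wide two-group comparison
#'
#' Applies [group_anova()] to every analysed fragment of a cohort fit and
#' flags (a) Bonferroni significance at `alpha` over the tested family and
#' (b) fragments with a group mean-methylation difference of at least
#' `min_mean_diff` percentage points, the filter used to shortlist
#' sex-differential fragments irrespective of significance.
#'
#' @param cohort A `"meth_cohort"`.
#' @param groups Group label per individual (named by individual or in
#'   cohort column order); exactly two groups.
#' @param min_mean_diff Mean-difference filter in percentage points
#'   (default 20).
#' @param alpha Family-wise level for the Bonferroni flag (default 0.05).
#' @return data.frame with one row per analysed fragment: `fragment_id`,
#'   `chrom`, group means, `mean_diff`, `F`, `p`,
#'   `significant_after_bonferroni`, `passes_mean_diff`.
#' @export
group_anova_cohort <- function(cohort, groups, min_mean_diff = 20,
                               alpha = 0.05) {
  stopifnot(inherits(cohort, "meth_cohort"))
  if (!is.null(names(groups))) groups <- groups[cohort$individuals]
  if (length(groups) != length(cohort$individuals))
    stop("one group label per individual is required")
  P <- methylation_matrix(cohort)
  lev <- sort(unique(as.character(groups)))
  if (length(lev) != 2L) stop("exactly two groups are required")
  rows <- lapply(seq_len(nrow(P)), function(i) {
    a <- group_anova(P[i, ], groups)
    data.frame(fragment_id = rownames(P)[i],
               mean_1 = a$group_means[[1L]], mean_2 = a$group_means[[2L]],
               mean_diff = a$mean_diff, F = a$F, p = a$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:3] <- paste0("mean_", lev)
  out$chrom <- cohort$fragments$chrom[match(out$fragment_id,
                                            cohort$fragments$fragment_id)]
  tested <- sum(!is.na(out$p))
  out$significant_after_bonferroni <- !is.na(out$p) &
    out$p <= bonferroni_threshold(alpha, max(tested, 1L))
  out$passes_mean_diff <- !is.na(out$mean_diff) & out$mean_diff >= min_mean_diff
  rownames(out) <- NULL
  out
}

#' Bland-Altman limits of agreement between technical replicates
#'
#' Quantifies replicate concordance of fragment methylation: the bias is
#' the mean of paired differences (A - B) and the 95% limits of agreement
#' are `bias +/- 1.96 * SD(differences)`.
#'
#' @param a,b Paired methylation percentages from the two libraries.
#' @return List with `bias`, `lower`, `upper`, `sd_diff`, `n`.
#' @export
bland_altman <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2L) stop("at least two complete pairs are required")
  d <- a - b
  bias <- mean(d); s <- sd(d)
  list(bias = bias, lower = bias - 1.96 * s, upper = bias + 1.96 * s,
       sd_diff = s, n = length(d))
}
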