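#' Yates-corrected chi-square test of a 2x2 table
#'
#' The continuity-corrected chi-square statistic
#' `N * (|ad - bc| - N/2)^2 / (r1 * r2 * c1 * c2)`, clamped to 0 when the
#' correction exceeds `|ad - bc|`, with the p-value from the df = 1 upper
#' tail.  Any zero margin gives `(0, 1)`.
#'
#' @param table A 2x2 numeric matrix of non-negative counts.
#' @return List with `chi2` and `p`.
#' @examples
#' yates_chi2(matrix(c(30, 10, 70, 90), 2))  # chi2 = 11.28
#' @export
yates_chi2 <- function(table) {
  if (!all(dim(table) == c(2L, 2L))) stop("a 2x2 table is required")
  if (any(table < 0)) stop("negative cell counts")
  a <- as.numeric(table[1, 1]); b <- as.numeric(table[1, 2])
  cc <- as.numeric(table[2, 1]); d <- as.numeric(table[2, 2])
  N <- a + b + cc + d
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc; c2 <- b + d
  if (N < 1 || r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0)
    return(list(chi2 = 0, p = 1))
  delta <- abs(a * d - b * cc)
  if (delta <= N / 2) return(list(chi2 = 0, p = 1))
  chi2 <- N * (delta - N / 2)^2 / (r1 * r2 * c1 * c2)
  list(chi2 = chi2, p = pchisq(chi2, 1L, lower.tail = FALSE))
}

#' Strong-overlap flag of fragments with a feature track
#'
#' A fragment counts as overlapping a feature track when at least
#' `min_frac` of its length (default 50%) is covered by the merged
#' feature intervals.
#'
#' @param fragments Fragment data.frame.
#' @param features Feature interval data.frame (`chrom`, `start`, `end`).
#' @param min_frac Minimum covered fraction, inclusive (default 0.5).
#' @return Logical vector along the fragments.
#' @export
feature_overlap_flag <- function(fragments, features, min_frac = 0.5) {
  if (nrow(features) == 0L) return(rep(FALSE, nrow(fragments)))
  features <- merge_intervals(features)
  covered <- numeric(nrow(fragments))
  for (ch in unique(fragments$chrom)) {
    fi <- which(fragments$chrom == ch)
    fe <- features[features$chrom == ch, , drop = FALSE]
    if (nrow(fe) == 0L) next
    fr_ir <- IRanges::IRanges(fragments$start[fi] + 1L, fragments$end[fi])
    ft_ir <- IRanges::IRanges(fe$start + 1L, fe$end)
    hits <- IRanges::findOverlaps(fr_ir, ft_ir)
    if (!length(hits)) next
    w <- BiocGenerics::width(IRanges::pintersect(
      fr_ir[S4Vectors::queryHits(hits)], ft_ir[S4Vectors::subjectHits(hits)]))
    agg <- rowsum(w, S4Vectors::queryHits(hits))
    covered[fi[as.integer(rownames(agg))]] <- agg[, 1L]
  }
  covered / (fragments$end - fragments$start) >= min_frac
}

#' Feature enrichment of iVMFs against non-variable fragments
#'
#' Builds the 2x2 table (iVMF vs non-variable) x (strong feature overlap
#' vs not) from [feature_overlap_flag()] counts and tests it with the
#' Yates-corrected chi-square.  Direction is `enriched` when the iVMF
#' overlap proportion exceeds the non-variable proportion at `p < 0.05`,
#' `depleted` for the reverse, else `none`.
#'
#' @param ivmf_fragments,nonvar_fragments Fragment data.frames for the two
#'   groups (drawn from the same analysed, category-matched universe).
#' @param features Feature track intervals.
#' @param min_frac Strong-overlap threshold (default 0.5).
#' @param feature_id Label carried into the result.
#' @return List with `feature_id`, `table`, `chi2`, `p`, `direction`,
#'   `prop_ivmf`, `prop_nonvar`.
#' @export
feature_enrichment <- function(ivmf_fragments, nonvar_fragments, features,
                               min_frac = 0.5, feature_id = "feature") {
  f1 <- feature_overlap_flag(ivmf_fragments, features, min_frac)
  f0 <- feature_overlap_flag(nonvar_fragments, features, min_frac)
  tab <- matrix(c(sum(f1), sum(f0), sum(!f1), sum(!f0)), 2L,
                dimnames = list(c("ivmf", "nonvar"), c("overlap", "no_overlap")))
  yc <- yates_chi2(tab)
  p1 <- if (length(f1)) mean(f1) else NA_real_
  p0 <- if (length(f0)) mean(f0) else NA_real_
  direction <- "none"
  if (!is.na(p1) && !is.na(p0) && yc$p < 0.05)
    direction <- if (p1 > p0) "enriched" else "depleted"
  list(feature_id = feature_id, table = tab, chi2 = yc$chi2, p = yc$p,
       direction = direction, prop_ivmf = p1, prop_nonvar = p0)
}

#' Chromosome-wise distribution test of iVMFs against the RR genome
#'
#' For each chromosome, tests whether the iVMF share on that chromosome
#' differs from its RR-genome share using a Yates-corrected 2x2 (this
#' chromosome vs all others) x (iVMF vs RR fragment counts).
#'
#' @param ivmf_counts Named vector of iVMF counts per chromosome.
#' @param rr_counts Named vector of RR-genome fragment counts per
#'   chromosome; chromosomes absent here are skipped with a warning.
#' @param alpha Flagging level (default 1e-4).
#' @return data.frame per chromosome: counts, shares (%), `chi2`, `p`,
#'   `direction` (at `p < alpha`), or zero rows for a single-chromosome
#'   genome.
#' @export
chromosome_distribution_test <- function(ivmf_counts, rr_counts, alpha = 1e-4) {
  miss <- setdiff(names(ivmf_counts), names(rr_counts))
  if (length(miss)) {
    warning("chromosome(s) absent from RR counts skipped: ",
            paste(miss, collapse = ", "))
    ivmf_counts <- ivmf_counts[setdiff(names(ivmf_counts), miss)]
  }
  chroms <- names(rr_counts)
  if (length(chroms) < 2L) {
    warning("chromosome-wise test undefined for a single chromosome")
    return(data.frame(chrom = character(), n_ivmf = integer(),
                      n_rr = integer(), pct_ivmf = numeric(),
                      pct_rr = numeric(), chi2 = numeric(), p = numeric(),
                      direction = character()))
  }
  iv <- setNames(rep(0L, length(chroms)), chroms)
  iv[names(ivmf_counts)] <- ivmf_counts
  K <- sum(iv); N <- sum(rr_counts)
  rows <- lapply(chroms, function(ch) {
    tab <- matrix(c(iv[[ch]], rr_counts[[ch]], K - iv[[ch]],
                    N - rr_counts[[ch]]), 2L)
    yc <- yates_chi2(tab)
    share_iv <- 100 * iv[[ch]] / K
    share_rr <- 100 * rr_counts[[ch]] / N
    data.frame(chrom = ch, n_ivmf = iv[[ch]], n_rr = rr_counts[[ch]],
               pct_ivmf = share_iv, pct_rr = share_rr,
               chi2 = yc$chi2, p = yc$p,
               direction = if (yc$p < alpha)
                 (if (share_iv > share_rr) "enriched" else "depleted")
               else "none",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hypergeometric gene-list overlap test
#'
#' Upper-tail probability of observing at least `k` common genes between
#' two lists drawn from a universe of `universe_n` genes.
#'
#' @param k Observed overlap.
#' @param list_a,list_b Sizes of the two lists.
#' @param universe_n Universe size (e.g. the number of protein-coding
#'   genes in the annotation).
#' @return The p-value `P(X >= k)`.
#' @export
hypergeometric_overlap <- function(k, list_a, list_b, universe_n) {
  if (list_a > universe_n || list_b > universe_n ||
      k > min(list_a, list_b) || k < 0)
    stop("inconsistent overlap-test sizes")
  phyper(k - 1, list_b, universe_n - list_b, list_a, lower.tail = FALSE)
}
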