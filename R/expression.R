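#' Gene expression across methylation bins
#'
#' Bins (fragment, individual) methylation percentages into the classes
#' 0-30%, 30-70% and >70% (left bin closed on its upper bound: `[0,30]`,
#' `(30,70]`, `(70,100]`), compares log-scale abundance across bins with a
#' one-way ANOVA, and runs an all-pairs Tukey HSD post-hoc with a
#' letters-style grouping (bins sharing no letter differ at `p < 0.05`).
#'
#' @param meth_pct Methylation percentage per observation.
#' @param abundance Matched expression abundance (FPKM-like); compared on
#'   the `log(abundance + offset)` scale.
#' @param breaks Bin edges (default `c(0, 30, 70, 100)`).
#' @param offset Pseudo-count added before the log (default 0.1).
#' @param alpha Level for the post-hoc letters (default 0.05).
#' @return List with `bins` (per-bin n, mean and median log-abundance,
#'   letter), `anova_F`, `anova_p`, `tukey` (pairwise table).  Bins with
#'   fewer than 2 observations are dropped with a warning; fewer than two
#'   usable bins yields the `NA` sentinel for the test.
#' @export
methylation_expression_bins <- function(meth_pct, abundance,
                                        breaks = c(0, 30, 70, 100),
                                        offset = 0.1, alpha = 0.05) {
  ok <- !is.na(meth_pct) & !is.na(abundance)
  meth_pct <- meth_pct[ok]; abundance <- abundance[ok]
  bin <- cut(meth_pct, breaks, include.lowest = TRUE, right = TRUE)
  la <- log(abundance + offset)
  counts <- table(bin)
  small <- names(counts)[counts < 2L]
  if (length(small)) {
    warning("bin(s) with < 2 observations dropped: ",
            paste(small, collapse = ", "))
    keep <- !(as.character(bin) %in% small) & !is.na(bin)
    bin <- droplevels(bin[keep]); la <- la[keep]
  } else {
    keep <- !is.na(bin); bin <- droplevels(bin[keep]); la <- la[keep]
  }
  bins <- data.frame(bin = levels(bin),
                     n = as.integer(table(bin)),
                     mean_log = as.numeric(tapply(la, bin, mean)),
                     median_log = as.numeric(tapply(la, bin, median)),
                     letter = NA_character_, stringsAsFactors = FALSE)
  out <- list(bins = bins, anova_F = NA_real_, anova_p = NA_real_,
              tukey = NULL)
  if (nlevels(bin) < 2L || var(la) == 0) return(out)
  fit <- aov(la ~ bin)
  an <- summary(fit)[[1L]]
  out$anova_F <- an$`F value`[1L]
  out$anova_p <- an$`Pr(>F)`[1L]
  tk <- TukeyHSD(fit)$bin
  out$tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                          p_adj = tk[, "p adj"], row.names = NULL,
                          stringsAsFactors = FALSE)
  out$bins$letter <- grouping_letters(levels(bin), out$tukey, alpha)
  out
}

# Letters-style display grouping: groups connected by non-significant
# pairwise differences share a letter (greedy clique cover; exact for the
# handful of bins used here).
grouping_letters <- function(groups, tukey, alpha = 0.05) {
  n <- length(groups)
  same <- diag(TRUE, n); dimnames(same) <- list(groups, groups)
  for (i in seq_len(nrow(tukey))) {
    gg <- strsplit(tukey$pair[i], "-", fixed = TRUE)[[1L]]
    if (all(gg %in% groups) && tukey$p_adj[i] >= alpha)
      same[gg[1L], gg[2L]] <- same[gg[2L], gg[1L]] <- TRUE
  }
  cliques <- list()
  for (i in seq_len(n)) {
    placed <- FALSE
    for (ci in seq_along(cliques)) {
      if (all(same[i, cliques[[ci]]])) {
        cliques[[ci]] <- c(cliques[[ci]], i); placed <- TRUE
      }
    }
    if (!placed) cliques[[length(cliques) + 1L]] <- i
  }
  letters_out <- rep("", n)
  for (ci in seq_along(cliques))
    letters_out[cliques[[ci]]] <- paste0(letters_out[cliques[[ci]]],
                                         letters[ci])
  letters_out
}

#' Methylation-expression association in TSS windows
#'
#' Assigns fragments (by midpoint) to distance windows around the TSS of
#' the nearest protein-coding gene (signed distance, positive upstream,
#' negative downstream, strand-aware) and, per window, runs the
#' methylation-bin ANOVA of [methylation_expression_bins()] on
#' (fragment, individual) methylation against the gene's abundance in the
#' same individual.
#'
#' @param fragments Fragment data.frame.
#' @param meth Methylation matrix (fragments x individuals, rownames =
#'   fragment ids, colnames = individual ids).
#' @param genes Gene table.
#' @param abundance data.frame `gene_id`, `individual_id`, `abundance`.
#' @param windows Named list of `c(from, to)` signed-distance windows in
#'   bp, fragment assigned when `from <= d < to`; default: downstream
#'   0-500 plus upstream 500 bp bands out to 3 kb.
#' @return data.frame per window with `n_pairs`, `anova_F`, `anova_p`
#'   (windows with no fragments are omitted).
#' @export
tss_window_association <- function(fragments, meth, genes, abundance,
                                   windows = NULL) {
  if (is.null(windows))
    windows <- list(down_0_500 = c(-500, 0), up_0_500 = c(0, 500),
                    up_500_1000 = c(500, 1000), up_1000_1500 = c(1000, 1500),
                    up_1500_2000 = c(1500, 2000), up_2000_2500 = c(2000, 2500),
                    up_2500_3000 = c(2500, 3000))
  genes <- genes[genes$biotype == "protein_coding", , drop = FALSE]
  mid <- (fragments$start + fragments$end) %/% 2L
  d <- rep(NA_real_, nrow(fragments)); gid <- rep(NA_character_, nrow(fragments))
  for (i in seq_len(nrow(fragments))) {
    g <- genes[genes$chrom == fragments$chrom[i], , drop = FALSE]
    if (!nrow(g)) next
    dd <- ifelse(g$strand == "+", g$tss - mid[i], mid[i] - g$tss)
    j <- which.min(abs(dd))
    d[i] <- dd[j]; gid[i] <- g$gene_id[j]
  }
  rows <- lapply(names(windows), function(w) {
    sel <- which(!is.na(d) & d >= windows[[w]][1L] & d < windows[[w]][2L])
    if (!length(sel)) return(NULL)
    mm <- meth[match(fragments$fragment_id[sel], rownames(meth)), ,
               drop = FALSE]
    pairs_m <- as.vector(mm)
    pairs_g <- rep(gid[sel], times = ncol(mm))
    pairs_i <- rep(colnames(mm), each = nrow(mm))
    ab <- abundance$abundance[match(paste(pairs_g, pairs_i),
                                    paste(abundance$gene_id,
                                          abundance$individual_id))]
    ok <- !is.na(pairs_m) & !is.na(ab)
    if (sum(ok) < 4L) return(NULL)
    res <- suppressWarnings(methylation_expression_bins(pairs_m[ok], ab[ok]))
    data.frame(window = w, n_pairs = sum(ok), anova_F = res$anova_F,
               anova_p = res$anova_p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(window = character(), n_pairs = integer(),
                      anova_F = numeric(), anova_p = numeric())
  rownames(out) <- NULL
  out
}

pooled_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L || sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(x)))
  ct <- cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Exon-level methylation-expression correlation
#'
#' Pearson correlation of exon methylation percentage against
#' `log2(read count + 1)`, per gene and pooled over all
#' (exon, individual) pairs with equal weight.
#'
#' @param exon_meth data.frame `exon_id`, `gene_id`, `individual_id`,
#'   `meth_pct`.
#' @param exon_counts data.frame `exon_id`, `individual_id`, `count`.
#' @return List with `pooled` (r, p, n) and `per_gene` data.frame.  Genes
#'   with fewer than 3 pairs or zero variance get the `NA` sentinel.
#' @export
exon_methylation_correlation <- function(exon_meth, exon_counts) {
  cnt <- exon_counts$count[match(paste(exon_meth$exon_id,
                                       exon_meth$individual_id),
                                 paste(exon_counts$exon_id,
                                       exon_counts$individual_id))]
  y <- log2(cnt + 1)
  pooled <- pooled_cor(exon_meth$meth_pct, y)
  per_gene <- do.call(rbind, lapply(split(seq_along(y), exon_meth$gene_id),
    function(ix) {
      pc <- pooled_cor(exon_meth$meth_pct[ix], y[ix])
      data.frame(gene_id = exon_meth$gene_id[ix[1L]], r = pc$r, p = pc$p,
                 n = pc$n, stringsAsFactors = FALSE)
    }))
  rownames(per_gene) <- NULL
  list(pooled = pooled, per_gene = per_gene)
}

#' iVMF methylation versus exon inclusion
#'
#' For iVMFs that directly overlap differentially used exons, correlates
#' fragment methylation with `log2(count + 1)` of the overlapped exon
#' over (iVMF, individual) pairs, and repeats the correlation against the
#' adjacent exons (previous and next in transcription order) as local
#' controls.  First/last exons lack one neighbour and are skipped for that
#' control only.
#'
#' @param ivmf_fragments Fragment data.frame of the iVMFs.
#' @param meth Methylation matrix (fragments x individuals).
#' @param exons Exon table with `rank` (transcription order).
#' @param exon_counts data.frame `exon_id`, `individual_id`, `count`,
#'   `is_differential`.
#' @return List with `overlap`, `upstream`, `downstream` (each r, p, n)
#'   and `pairs`, the underlying long table.  No overlapping differential
#'   exon yields empty results rather than an error.
#' @export
ivmf_exon_inclusion <- function(ivmf_fragments, meth, exons, exon_counts) {
  diff_ex <- unique(exon_counts$exon_id[exon_counts$is_differential %in% TRUE])
  ex <- exons[exons$exon_id %in% diff_ex, , drop = FALSE]
  pairs <- list()
  for (i in seq_len(nrow(ivmf_fragments))) {
    hit <- which(ex$chrom == ivmf_fragments$chrom[i] &
                   ex$start < ivmf_fragments$end[i] &
                   ex$end > ivmf_fragments$start[i])
    if (!length(hit)) next
    w <- pmin(ex$end[hit], ivmf_fragments$end[i]) -
      pmax(ex$start[hit], ivmf_fragments$start[i])
    e <- ex[hit[which.max(w)], ]
    prev_id <- exons$exon_id[exons$gene_id == e$gene_id &
                               exons$rank == e$rank - 1L]
    next_id <- exons$exon_id[exons$gene_id == e$gene_id &
                               exons$rank == e$rank + 1L]
    mrow <- meth[match(ivmf_fragments$fragment_id[i], rownames(meth)), ]
    pairs[[length(pairs) + 1L]] <-
      data.frame(fragment_id = ivmf_fragments$fragment_id[i],
                 exon_id = e$exon_id,
                 prev_exon = if (length(prev_id)) prev_id[1L] else NA_character_,
                 next_exon = if (length(next_id)) next_id[1L] else NA_character_,
                 individual_id = names(mrow), meth_pct = as.numeric(mrow),
                 stringsAsFactors = FALSE)
  }
  empty <- list(r = NA_real_, p = NA_real_, n = 0L)
  if (!length(pairs))
    return(list(overlap = empty, upstream = empty, downstream = empty,
                pairs = data.frame()))
  pr <- do.call(rbind, pairs)
  rownames(pr) <- NULL
  count_of <- function(exon_id, ind)
    exon_counts$count[match(paste(exon_id, ind),
                            paste(exon_counts$exon_id,
                                  exon_counts$individual_id))]
  y0 <- log2(count_of(pr$exon_id, pr$individual_id) + 1)
  yu <- log2(count_of(pr$prev_exon, pr$individual_id) + 1)
  yd <- log2(count_of(pr$next_exon, pr$individual_id) + 1)
  list(overlap = pooled_cor(pr$meth_pct, y0),
       upstream = pooled_cor(pr$meth_pct, yu),
       downstream = pooled_cor(pr$meth_pct, yd),
       pairs = pr)
}
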