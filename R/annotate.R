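#' Classify fragments by gene context
#'
#' Places each fragment relative to protein-coding gene models.  A
#' fragment overlapping a gene is `tss_overlap` when it covers the
#' transcription start site, otherwise `exon` (entirely within one exon),
#' `intron` (no exon overlap), or the appropriate junction class
#' (`exon_intron_boundary` when it runs past an exon's 3' end into the
#' intron, `intron_exon_boundary` when it enters the exon from the
#' upstream intron; both in transcription orientation).  A fragment
#' overlapping no gene is assigned to the nearest gene for which it lies
#' strand-aware upstream of the TSS and binned by the TSS-to-closest-edge
#' distance: `promoter_0_2kb`, `promoter_2_5kb`, `upstream_5_10kb`,
#' `distant_gt10kb`.  Promoters here extend up to 5 kb upstream of the
#' gene start.  Ties between equidistant genes are broken by lexicographic
#' gene id with a warning.
#'
#' @param fragments Fragment data.frame (0-based half-open).
#' @param genes Gene table (see [read_genes_gtf()]); restricted internally
#'   to `biotype == "protein_coding"`.
#' @param exons Exon table.
#' @return data.frame `fragment_id`, `gene_id`, `category`,
#'   `distance_to_tss` (bp from the TSS to the fragment's closest edge;
#'   positive upstream, negative downstream, 0 for gene overlap).  With an
#'   empty gene set every fragment gets the `unassigned` sentinel.
#' @export
classify_gene_context <- function(fragments, genes, exons) {
  genes <- genes[genes$biotype == "protein_coding", , drop = FALSE]
  n <- nrow(fragments)
  out <- data.frame(fragment_id = fragments$fragment_id,
                    gene_id = NA_character_, category = "unassigned",
                    distance_to_tss = NA_real_, stringsAsFactors = FALSE)
  if (nrow(genes) == 0L) return(out)
  ties <- 0L
  for (i in seq_len(n)) {
    fs <- fragments$start[i]; fe <- fragments$end[i]
    ch <- fragments$chrom[i]
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0L) next
    ov <- which(g$start < fe & g$end > fs)
    if (length(ov)) {
      w <- pmin(g$end[ov], fe) - pmax(g$start[ov], fs)
      best <- ov[w == max(w)]
      if (length(best) > 1L) { ties <- ties + 1L; best <- best[order(g$gene_id[best])] }
      gi <- best[1L]
      out$gene_id[i] <- g$gene_id[gi]
      out$distance_to_tss[i] <- 0
      if (fs <= g$tss[gi] && g$tss[gi] < fe) {
        out$category[i] <- "tss_overlap"
      } else {
        ex <- exons[exons$gene_id == g$gene_id[gi], , drop = FALSE]
        hit <- which(ex$start < fe & ex$end > fs)
        if (!length(hit)) {
          out$category[i] <- "intron"
        } else if (any(ex$start[hit] <= fs & fe <= ex$end[hit])) {
          out$category[i] <- "exon"
        } else {
          past_3p <- if (g$strand[gi] == "+") fe > max(ex$end[hit])
                     else fs < min(ex$start[hit])
          out$category[i] <- if (past_3p) "exon_intron_boundary"
                             else "intron_exon_boundary"
        }
      }
    } else {
      up <- if (any(g$strand == "+")) which(g$strand == "+" & fe <= g$tss) else integer()
      dist_up <- g$tss[up] - (fe - 1L)
      up2 <- which(g$strand == "-" & fs > g$tss)
      dist_up <- c(dist_up, fs - g$tss[up2])
      cand <- c(up, up2)
      if (length(cand)) {
        best <- which(dist_up == min(dist_up))
        if (length(best) > 1L) {
          ties <- ties + 1L
          best <- best[order(g$gene_id[cand[best]])]
        }
        d <- dist_up[best[1L]]
        out$gene_id[i] <- g$gene_id[cand[best[1L]]]
        out$distance_to_tss[i] <- d
        out$category[i] <-
          if (d <= 2000) "promoter_0_2kb"
          else if (d <= 5000) "promoter_2_5kb"
          else if (d <= 10000) "upstream_5_10kb"
          else "distant_gt10kb"
      } else {
        # downstream of every gene on the chromosome
        dd <- pmin(abs(fs - g$tss), abs(g$tss - (fe - 1L)))
        gi <- which.min(dd)
        out$gene_id[i] <- g$gene_id[gi]
        out$distance_to_tss[i] <- -dd[gi]
        out$category[i] <- "distant_gt10kb"
      }
    }
  }
  if (ties > 0L)
    warning(ties, " fragment(s) had equidistant genes; ties broken by gene id")
  out
}

#' Classify fragments by CpG-island context
#'
#' Assigns each fragment, by its midpoint, to the CGI core, the shores
#' (the 2 kb bands flanking the core) or the shelves (the next 2 kb bands
#' beyond the shores); fragments further than 4 kb from any island edge
#' are `none`.  The nearest island wins.
#'
#' @param fragments Fragment data.frame.
#' @param cgi CGI interval data.frame (`chrom`, `start`, `end`); merged
#'   internally if overlapping.
#' @return Character vector of `core` / `shore` / `shelf` / `none` along
#'   the fragments.
#' @export
classify_cgi_context <- function(fragments, cgi) {
  cgi <- merge_intervals(cgi)
  mid <- (fragments$start + fragments$end) %/% 2L
  out <- rep("none", nrow(fragments))
  for (i in seq_len(nrow(fragments))) {
    cc <- cgi[cgi$chrom == fragments$chrom[i], , drop = FALSE]
    if (nrow(cc) == 0L) next
    inside <- cc$start <= mid[i] & mid[i] < cc$end
    if (any(inside)) { out[i] <- "core"; next }
    d <- ifelse(mid[i] < cc$start, cc$start - mid[i], mid[i] - (cc$end - 1L))
    dmin <- min(d)
    out[i] <- if (dmin <= 2000) "shore" else if (dmin <= 4000) "shelf" else "none"
  }
  out
}

merge_intervals <- function(x) {
  x <- x[order(x$chrom, x$start), , drop = FALSE]
  if (nrow(x) < 2L) return(x)
  keep <- list()
  cur <- x[1L, ]
  for (i in 2:nrow(x)) {
    if (x$chrom[i] == cur$chrom && x$start[i] <= cur$end) {
      cur$end <- max(cur$end, x$end[i])
    } else {
      keep[[length(keep) + 1L]] <- cur
      cur <- x[i, ]
    }
  }
  keep[[length(keep) + 1L]] <- cur
  out <- do.call(rbind, keep)
  rownames(out) <- NULL
  out
}

#' Variability score of a feature or gene
#'
#' The fraction of a unit's analysed fragments that are iVMFs:
#' `vs = n_ivmf / n_analysed`, ranging 0-1.
#'
#' @param is_ivmf Logical vector over the unit's analysed fragments.
#' @return List with `n_analysed`, `n_ivmf`, `vs`.
#' @export
variability_score <- function(is_ivmf) {
  is_ivmf <- is_ivmf[!is.na(is_ivmf)]
  if (!length(is_ivmf)) stop("variability score needs at least one analysed fragment")
  list(n_analysed = length(is_ivmf), n_ivmf = sum(is_ivmf),
       vs = sum(is_ivmf) / length(is_ivmf))
}

#' Per-gene variability scores
#'
#' Associates analysed fragments with genes via a gene-context assignment
#' (no limit on how far upstream a fragment may lie for gene-level
#' scoring, unless `categories` restricts to a region class) and computes
#' each gene's variability score.
#'
#' @param fit An `"ivmf_fit"`.
#' @param assignment Output of [classify_gene_context()] on the analysed
#'   fragments.
#' @param categories Optional subset of context categories defining a
#'   region class (e.g. promoter or gene body); default uses all assigned
#'   fragments.
#' @param autosomal_only Restrict to autosomal fragments (default TRUE).
#' @return data.frame `gene_id`, `n_analysed`, `n_ivmf`, `vs`, sorted by
#'   decreasing `n_ivmf`.
#' @export
gene_variability_scores <- function(fit, assignment, categories = NULL,
                                    autosomal_only = TRUE) {
  res <- fit$results
  a <- assignment[match(res$fragment_id, assignment$fragment_id), , drop = FALSE]
  keep <- !is.na(a$gene_id)
  if (autosomal_only) keep <- keep & res$autosomal
  if (!is.null(categories)) keep <- keep & a$category %in% categories
  gid <- a$gene_id[keep]; iv <- res$is_ivmf[keep] %in% TRUE
  if (!length(gid))
    return(data.frame(gene_id = character(), n_analysed = integer(),
                      n_ivmf = integer(), vs = numeric()))
  n_a <- tapply(iv, gid, length)
  n_i <- tapply(iv, gid, sum)
  out <- data.frame(gene_id = names(n_a), n_analysed = as.integer(n_a),
                    n_ivmf = as.integer(n_i),
                    vs = as.numeric(n_i / n_a), stringsAsFactors = FALSE)
  out <- out[order(-out$n_ivmf, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call variably methylated genes
#'
#' A gene (or a gene's region class) is a VMG when it has at least
#' `min_ivmfs` associated iVMFs and a variability score of at least
#' `min_vs`; units with fewer than `min_ivmfs` iVMFs are not considered.
#'
#' @param scores data.frame from [gene_variability_scores()].
#' @param min_ivmfs Minimum associated iVMFs (default 3).
#' @param min_vs Minimum variability score (default 0.5).
#' @return The qualifying rows of `scores`.
#' @export
call_vmgs <- function(scores, min_ivmfs = 3L, min_vs = 0.5) {
  out <- scores[scores$n_ivmf >= min_ivmfs & scores$vs >= min_vs, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Median methylation per genomic feature category
#'
#' Summarises mean fragment methylation by context category and tests for
#' across-category differences with a one-way ANOVA.
#'
#' @param mean_pct Mean methylation percentage per fragment.
#' @param category Feature category per fragment (empty categories are
#'   omitted).
#' @return List with `medians` (named vector), `counts`, `anova_F`,
#'   `anova_p` (`NA` sentinel when fewer than two categories are present
#'   or the within-category variance is zero).
#' @export
summarize_methylation_by_feature <- function(mean_pct, category) {
  ok <- !is.na(mean_pct) & !is.na(category)
  mean_pct <- mean_pct[ok]; category <- as.character(category)[ok]
  med <- tapply(mean_pct, category, median)
  counts <- table(category)
  out <- list(medians = med, counts = counts,
              anova_F = NA_real_, anova_p = NA_real_)
  usable <- names(counts)[counts >= 2L]
  if (length(usable) >= 2L) {
    sel <- category %in% usable
    if (var(mean_pct[sel]) > 0 &&
        any(tapply(mean_pct[sel], category[sel], var) > 0)) {
      fit <- oneway.test(mean_pct[sel] ~ factor(category[sel]),
                         var.equal = TRUE)
      out$anova_F <- unname(fit$statistic)
      out$anova_p <- fit$p.value
    }
  }
  out
}
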