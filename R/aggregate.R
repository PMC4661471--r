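#' Aggregate per-CpG calls to fragments for one individual
#'
#' Assigns every CpG call to the unique RR fragment whose half-open
#' interval contains its position (calls outside all fragments are
#' discarded) and sums methylated and unmethylated read observations over
#' the fragment, following the fragment-as-unit convention: the fragment's
#' methylation proportion is the total number of methylated CpG
#' observations in all reads divided by the total number of CpG
#' observations.
#'
#' @param calls Call data.frame from [read_cpg_calls()] (0-based `pos`).
#' @param fragments Fragment data.frame (non-overlapping per chromosome).
#' @param min_reads Per-CpG coverage threshold used to count qualifying
#'   CpGs (default 10).
#' @return data.frame with one row per fragment that received at least one
#'   call: `fragment_id`, `m`, `u`, `covered_cpgs` (CpG positions with
#'   coverage >= `min_reads`), `n_cpgs_covered` (CpG positions with any
#'   coverage), `methylation_pct`.
#' @export
aggregate_fragment_methylation <- function(calls, fragments, min_reads = 10L) {
  if (nrow(calls) == 0L)
    return(data.frame(fragment_id = character(), m = integer(), u = integer(),
                      covered_cpgs = integer(), n_cpgs_covered = integer(),
                      methylation_pct = numeric()))
  frag_of <- rep(NA_integer_, nrow(calls))
  for (ch in unique(calls$chrom)) {
    fi <- which(fragments$chrom == ch)
    if (!length(fi)) next
    fi <- fi[order(fragments$start[fi])]
    ci <- which(calls$chrom == ch)
    slot <- findInterval(calls$pos[ci], fragments$start[fi])
    ok <- slot >= 1L & calls$pos[ci] < fragments$end[fi][pmax(slot, 1L)]
    frag_of[ci[ok]] <- fi[slot[ok]]
  }
  keep <- !is.na(frag_of)
  if (!any(keep))
    return(data.frame(fragment_id = character(), m = integer(), u = integer(),
                      covered_cpgs = integer(), n_cpgs_covered = integer(),
                      methylation_pct = numeric()))
  fid <- fragments$fragment_id[frag_of[keep]]
  cov <- calls$meth[keep] + calls$unmeth[keep]
  agg <- rowsum(cbind(m = calls$meth[keep], u = calls$unmeth[keep],
                      covered_cpgs = as.integer(cov >= min_reads),
                      n_cpgs_covered = as.integer(cov > 0L)),
                fid, reorder = FALSE)
  out <- data.frame(fragment_id = rownames(agg), agg, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$methylation_pct <- ifelse(out$m + out$u > 0, 100 * out$m / (out$m + out$u),
                                NA_real_)
  out
}

#' Fragment qualification for one individual
#'
#' The inclusion filter applied before cohort assembly.  In the default
#' `"per_cpg"` reading a fragment qualifies when at least `min_cpgs` of its
#' CpG sites each carry `min_reads` or more reads; the alternative
#' `"fragment_total"` reading requires `min_cpgs` covered CpGs and
#' `min_reads` total read observations over the fragment, and is provided
#' for sensitivity analysis.
#'
#' @param fm Aggregated data.frame from [aggregate_fragment_methylation()].
#' @param min_cpgs Minimum qualifying CpG sites (default 2).
#' @param min_reads Per-CpG (or fragment-total) read threshold (default 10).
#' @param mode `"per_cpg"` (default) or `"fragment_total"`.
#' @return Logical vector along the rows of `fm`.
#' @export
qualify_fragment <- function(fm, min_cpgs = 2L, min_reads = 10L,
                             mode = c("per_cpg", "fragment_total")) {
  mode <- match.arg(mode)
  if (mode == "per_cpg") fm$covered_cpgs >= min_cpgs
  else fm$n_cpgs_covered >= min_cpgs & (fm$m + fm$u) >= min_reads
}

new_meth_cohort <- function(M, U, CC, fragments, individuals,
                            min_individuals, min_cpgs, min_reads, mode) {
  qualified <- if (mode == "per_cpg") CC >= min_cpgs
               else matrix(FALSE, nrow(M), ncol(M))  # caller overrides
  n_qual <- rowSums(qualified)
  analysed_ids <- fragments$fragment_id[n_qual >= min_individuals]
  structure(list(M = M, U = U, covered_cpgs = CC, qualified = qualified,
                 fragments = fragments, individuals = individuals,
                 analysed_ids = analysed_ids,
                 min_individuals = min_individuals, min_cpgs = min_cpgs,
                 min_reads = min_reads, mode = mode),
            class = "meth_cohort")
}

#' Assemble the cohort analysed-fragment matrix
#'
#' Combines per-individual aggregated fragment tables into count matrices,
#' applies the qualification filter per (fragment, individual), and defines
#' the analysed set: fragments qualifying in at least `min_individuals`
#' individuals.
#'
#' @param tables Named list (one element per individual) of data.frames
#'   from [aggregate_fragment_methylation()].
#' @param fragments RR fragment data.frame; a `n_cpgs` column (e.g. from
#'   [locate_cpgs()] counts) enables the analysed-CpG total in the summary.
#' @param min_individuals Minimum qualifying individuals for a fragment to
#'   be analysed (default 9).
#' @param min_cpgs,min_reads,mode Qualification parameters, see
#'   [qualify_fragment()].
#' @return An object of class `"meth_cohort"`: matrices `M`, `U`,
#'   `covered_cpgs` (fragments x individuals), logical `qualified`, the
#'   `fragments` table, `individuals`, `analysed_ids` and the filter
#'   settings.
#' @export
assemble_cohort <- function(tables, fragments, min_individuals = 9L,
                            min_cpgs = 2L, min_reads = 10L,
                            mode = c("per_cpg", "fragment_total")) {
  mode <- match.arg(mode)
  if (length(tables) < 2L) stop("need at least two individuals")
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    names(tables) <- paste0("S", seq_along(tables))
  if (min_individuals > length(tables))
    stop("min_individuals exceeds the number of individuals")
  ids <- fragments$fragment_id
  k <- length(tables)
  M <- U <- CC <- matrix(0L, length(ids), k,
                         dimnames = list(ids, names(tables)))
  qualified <- matrix(FALSE, length(ids), k, dimnames = list(ids, names(tables)))
  for (j in seq_len(k)) {
    t_j <- tables[[j]]
    ri <- match(t_j$fragment_id, ids)
    ok <- !is.na(ri)
    M[ri[ok], j] <- t_j$m[ok]
    U[ri[ok], j] <- t_j$u[ok]
    CC[ri[ok], j] <- t_j$covered_cpgs[ok]
    qualified[ri[ok], j] <- qualify_fragment(t_j[ok, , drop = FALSE],
                                             min_cpgs, min_reads, mode)
  }
  out <- new_meth_cohort(M, U, CC, fragments, names(tables),
                         min_individuals, min_cpgs, min_reads, mode)
  out$qualified <- qualified
  out$analysed_ids <- ids[rowSums(qualified) >= min_individuals]
  out
}

#' @export
print.meth_cohort <- function(x, ...) {
  cat(sprintf("RRBS cohort: %d individuals, %d RR fragments, %d analysed (qualified in >= %d individuals)\n",
              length(x$individuals), nrow(x$fragments),
              length(x$analysed_ids), x$min_individuals))
  cat("  qualifying fragments per individual:\n")
  print(colSums(x$qualified))
  if (!is.null(x$fragments$n_cpgs)) {
    idx <- match(x$analysed_ids, x$fragments$fragment_id)
    cat(sprintf("  analysed CpG sites: %d\n", sum(x$fragments$n_cpgs[idx])))
  }
  invisible(x)
}

#' Per-individual fragment methylation percentages
#'
#' @param cohort A `"meth_cohort"`.
#' @param analysed_only Restrict rows to the analysed set (default TRUE).
#' @param qualified_only Mask entries from non-qualified (fragment,
#'   individual) pairs as `NA` (default TRUE).
#' @return Matrix of methylation percentages (fragments x individuals).
#' @export
methylation_matrix <- function(cohort, analysed_only = TRUE,
                               qualified_only = TRUE) {
  tot <- cohort$M + cohort$U
  P <- 100 * cohort$M / ifelse(tot > 0, tot, NA)
  if (qualified_only) P[!cohort$qualified] <- NA_real_
  if (analysed_only)
    P <- P[rownames(P) %in% cohort$analysed_ids, , drop = FALSE]
  P
}
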