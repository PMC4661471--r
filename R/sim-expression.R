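#' Simulate expression tables coupled to fragment methylation
#'
#' Generates a gene-level abundance table (FPKM-like) and an exon-level
#' read-count table for the synthetic cohort, with two planted effects:
#'
#' * genes whose TSS window contains a variable fragment get abundance
#'   inversely related to that fragment's per-individual methylation
#'   (promoter-style repression);
#' * exons linked to a variable fragment in the truth table
#'   (`linked_exon`) get `log2` read counts correlated with the
#'   fragment's per-individual methylation at the target
#'   `expression_coupling`; all other exons, including the neighbours of
#'   linked exons, are uncoupled.
#'
#' The coupling is built on the pooled scale: linked-pair methylation is
#' standardised over all (linked exon, individual) pairs and mixed with
#' independent Gaussian noise as `rho * z + sqrt(1 - rho^2) * e`, so the
#' pooled Pearson correlation targets `rho` directly.  Linked exons carry
#' `is_differential = TRUE`.
#'
#' @param genome_sim A `"sim_genome"`.
#' @param meth_sim The matching `"sim_methylome"`.
#' @param config A [sim_config()]; defaults to `meth_sim$config`.
#' @param tss_window Signed-distance window (bp, positive upstream of the
#'   TSS) whose variable fragments drive gene abundance; default
#'   `c(-500, 0)`, i.e. 0-500 bp downstream of the gene start.
#' @return List of class `"sim_expression"`: `gene_abundance`
#'   (`gene_id`, `individual_id`, `abundance`), `exon_counts` (`exon_id`,
#'   `gene_id`, `individual_id`, `count`, `is_differential`), `linked`
#'   (fragment-exon links used).
#' @export
simulate_expression <- function(genome_sim, meth_sim,
                                config = meth_sim$config,
                                tss_window = c(-500, 0)) {
  stopifnot(inherits(meth_sim, "sim_methylome"))
  genes <- genome_sim$genes[genome_sim$genes$biotype == "protein_coding", ,
                            drop = FALSE]
  exons <- genome_sim$exons[genome_sim$exons$gene_id %in% genes$gene_id, ,
                            drop = FALSE]
  individuals <- meth_sim$individuals
  truth <- meth_sim$truth
  tm <- as.matrix(truth[, individuals, drop = FALSE])
  rownames(tm) <- truth$fragment_id
  frags <- meth_sim$fragments
  rho <- config$expression_coupling
  set.seed(config$seed + 2L)

  # gene abundance: inverse coupling to variable-fragment methylation in
  # the TSS window, log-normal noise elsewhere
  mid <- (frags$start + frags$end) %/% 2L
  base_g <- rnorm(nrow(genes), 3, 1)
  ab <- matrix(NA_real_, nrow(genes), length(individuals),
               dimnames = list(genes$gene_id, individuals))
  for (gi in seq_len(nrow(genes))) {
    d <- if (genes$strand[gi] == "+") genes$tss[gi] - mid else mid - genes$tss[gi]
    sel <- which(frags$chrom == genes$chrom[gi] &
                   d >= tss_window[1L] & d < tss_window[2L])
    noise <- rnorm(length(individuals), 0, 0.4)
    if (length(sel)) {
      mprom <- colMeans(tm[frags$fragment_id[sel], , drop = FALSE])
      ab[gi, ] <- exp(base_g[gi] - 2.5 * mprom / 100 + noise)
    } else {
      ab[gi, ] <- exp(base_g[gi] + noise)
    }
  }
  gene_abundance <- data.frame(
    gene_id = rep(genes$gene_id, times = length(individuals)),
    individual_id = rep(individuals, each = nrow(genes)),
    abundance = as.vector(ab), stringsAsFactors = FALSE)

  # exon counts
  links <- truth[truth$is_variable & !is.na(truth$linked_exon),
                 c("fragment_id", "linked_exon")]
  links <- links[!duplicated(links$linked_exon), , drop = FALSE]
  links <- links[links$linked_exon %in% exons$exon_id, , drop = FALSE]
  lk_meth <- tm[links$fragment_id, , drop = FALSE]       # links x individuals
  z <- if (nrow(links) && sd(as.vector(lk_meth)) > 0)
    (lk_meth - mean(lk_meth)) / sd(as.vector(lk_meth)) else lk_meth * 0
  cnt <- matrix(NA_real_, nrow(exons), length(individuals),
                dimnames = list(exons$exon_id, individuals))
  mu_e <- rnorm(nrow(exons), 8, 1)
  for (j in seq_along(individuals)) {
    eps <- rnorm(nrow(exons), 0, 1)
    log2c <- mu_e + 0.8 * eps
    li <- match(links$linked_exon, exons$exon_id)
    if (length(li))
      log2c[li] <- 8 + 2 * (rho * z[, j] + sqrt(1 - rho^2) * rnorm(nrow(links)))
    cnt[, j] <- pmax(0, round(2^log2c))
  }
  exon_counts <- data.frame(
    exon_id = rep(exons$exon_id, times = length(individuals)),
    gene_id = rep(exons$gene_id, times = length(individuals)),
    individual_id = rep(individuals, each = nrow(exons)),
    count = as.vector(cnt),
    is_differential = rep(exons$exon_id %in% links$linked_exon,
                          times = length(individuals)),
    stringsAsFactors = FALSE)
  structure(list(gene_abundance = gene_abundance, exon_counts = exon_counts,
                 linked = links, config = config),
            class = "sim_expression")
}

#' @export
print.sim_expression <- function(x, ...) {
  cat(sprintf("Synthetic expression: %d genes x %d individuals; %d exon-fragment links (coupling %.2f)\n",
              length(unique(x$gene_abundance$gene_id)),
              length(unique(x$gene_abundance$individual_id)),
              nrow(x$linked), x$config$expression_coupling))
  invisible(x)
}

#' Write synthetic expression tables
#'
#' @param sim A `"sim_expression"`.
#' @param outdir Output directory.
#' @return Invisibly, the two file paths.
#' @export
write_expression_files <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pa <- file.path(outdir, "gene_abundance.tsv")
  pe <- file.path(outdir, "exon_counts.tsv")
  write.table(sim$gene_abundance, pa, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$exon_counts, pe, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(gene_abundance = pa, exon_counts = pe))
}
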