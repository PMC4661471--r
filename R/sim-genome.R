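#' Generate a synthetic genome with genes and CpG islands
#'
#' Builds a miniature genome for end-to-end testing of the fragment
#' pipeline: random background sequence with MspI (CCGG) sites planted at a
#' requested density, CG-rich CpG islands at about half of the promoters
#' plus a few intergenic ones, and a regular array of gene models (three
#' exons each, alternating strand, mostly protein-coding with occasional
#' non-coding genes to exercise biotype filtering).  When `config$sexes` is
#' set and the cohort has at least four members, a pseudo-X chromosome is
#' appended; its fragments can be made sex-differential by
#' [simulate_methylome()].
#'
#' CCGG occurrences are controlled exactly: after assembly every occurrence
#' that was not deliberately planted is destroyed by a single-base
#' substitution, so `ccgg_density = 0` yields a genome with no CCGG
#' substring at all.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `"sim_genome"` with elements `genome` (named
#'   character vector), `genes`, `exons`, `cgi` (0-based half-open
#'   data.frames) and `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  if (!is.null(config$sexes) && config$n_individuals >= 4L)
    chroms <- c(chroms, "chrX")
  genome <- character(0)
  genes <- list(); exons <- list(); cgi <- list()
  for (ch in chroms) {
    L <- config$chrom_length
    base <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                   prob = c(0.3, 0.2, 0.2, 0.3))

    gm <- layout_genes(ch, L)
    # CG-rich islands over half the promoters plus two intergenic ones
    isl <- gm$genes[seq_len(nrow(gm$genes)) %% 2L == 1L, , drop = FALSE]
    isl_start <- pmax(0L, isl$tss - 300L)
    inter <- sort(sample.int(L - 800L, 2L))
    cgi_df <- data.frame(chrom = ch,
                         start = c(isl_start, inter),
                         end = c(isl_start + 600L, inter + 600L))
    cgi_df <- cgi_df[order(cgi_df$start), ]
    cgi_df <- cgi_df[cgi_df$end <= L, , drop = FALSE]
    for (i in seq_len(nrow(cgi_df))) {
      w <- cgi_df$end[i] - cgi_df$start[i]
      units <- sample(c("CG", "CA", "TG", "AC", "GT"), ceiling(w / 2),
                      replace = TRUE, prob = c(0.5, 0.125, 0.125, 0.125, 0.125))
      rich <- strsplit(paste(units, collapse = ""), "")[[1L]][seq_len(w)]
      base[(cgi_df$start[i] + 1L):cgi_df$end[i]] <- rich
    }

    # plant CCGG sites at the requested density, >= 10 bp apart
    n_sites <- rpois(1L, config$ccgg_density * L / 1000)
    planted <- integer(0)
    if (n_sites > 0L) {
      cand <- sort(sample.int(L - 4L, min(n_sites, floor((L - 4L) / 10))))
      keep <- c(TRUE, diff(cand) >= 10L)
      planted <- cand[keep] - 1L            # 0-based motif offsets
      for (p in planted) base[(p + 1L):(p + 4L)] <- c("C", "C", "G", "G")
    }

    seq_chr <- paste(base, collapse = "")
    seq_chr <- scrub_unplanted_ccgg(seq_chr, planted)
    genome[[ch]] <- seq_chr
    genes[[ch]] <- gm$genes
    exons[[ch]] <- gm$exons
    cgi[[ch]] <- cgi_df
  }
  structure(list(genome = genome,
                 genes = do.call(rbind, c(genes, list(make.row.names = FALSE))),
                 exons = do.call(rbind, c(exons, list(make.row.names = FALSE))),
                 cgi = do.call(rbind, c(cgi, list(make.row.names = FALSE))),
                 config = config),
            class = "sim_genome")
}

# Regular gene cassettes: 3 exons of 400 bp separated by 900 bp introns
# (gene span 3000 bp), intergenic gap 4000 bp, strands alternating, every
# seventh gene non-coding.
layout_genes <- function(chrom, L) {
  period <- 7000L; margin <- 2000L
  starts <- seq(margin, L - margin - 3000L, by = period)
  n <- length(starts)
  if (n == 0L) stop("chromosome too short to place genes")
  strand <- rep(c("+", "-"), length.out = n)
  biotype <- ifelse(seq_len(n) %% 7L == 0L, "lincRNA", "protein_coding")
  gid <- sprintf("%s_G%03d", chrom, seq_len(n))
  genes <- data.frame(gene_id = gid, chrom = chrom, start = starts,
                      end = starts + 3000L, strand = strand,
                      biotype = biotype,
                      tss = ifelse(strand == "+", starts, starts + 3000L - 1L),
                      stringsAsFactors = FALSE)
  ex <- lapply(seq_len(n), function(i) {
    es <- starts[i] + c(0L, 1300L, 2600L)
    ord <- if (strand[i] == "+") 1:3 else 3:1
    data.frame(gene_id = gid[i],
               exon_id = sprintf("%s_E%d", gid[i], ord),
               chrom = chrom, start = es, end = es + 400L,
               rank = ord, stringsAsFactors = FALSE)
  })
  list(genes = genes, exons = do.call(rbind, ex))
}

# Destroy every CCGG occurrence that is not a planted site by mutating one
# of its bases (outside any planted interval) to A.  A cannot take part in
# a CCGG, so no new occurrence can be created.
scrub_unplanted_ccgg <- function(seq_chr, planted) {
  for (pass in 1:5) {
    occ <- gregexpr("CCGG", seq_chr, fixed = TRUE)[[1L]]
    occ <- occ[occ > 0L] - 1L               # 0-based
    rogue <- setdiff(occ, planted)
    if (!length(rogue)) return(seq_chr)
    v <- strsplit(seq_chr, "")[[1L]]
    in_planted <- function(i0)             # 0-based base index
      length(planted) && any(i0 >= planted & i0 < planted + 4L)
    for (o in rogue) {
      for (i0 in o:(o + 3L)) {
        if (!in_planted(i0)) { v[i0 + 1L] <- "A"; break }
      }
    }
    seq_chr <- paste(v, collapse = "")
  }
  seq_chr
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("Synthetic genome: %d chromosome(s), %d genes (%d protein-coding), %d CGIs\n",
              length(x$genome), nrow(x$genes),
              sum(x$genes$biotype == "protein_coding"), nrow(x$cgi)))
  invisible(x)
}

#' Write synthetic genome annotation files
#'
#' Writes the genome FASTA, a GTF of gene and exon features, a BED12 of
#' genes and a BED3 of CpG islands into `outdir`, in the dialects the
#' package readers consume.
#'
#' @param sim A `"sim_genome"` object.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_genome_files <- function(sim, outdir) {
  stopifnot(inherits(sim, "sim_genome"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(outdir, "genome.fa"),
             gtf = file.path(outdir, "genes.gtf"),
             bed12 = file.path(outdir, "genes.bed"),
             cgi = file.path(outdir, "cgi.bed"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$genome), paths[["fasta"]])
  write_genes_gtf(sim$genes, sim$exons, paths[["gtf"]])
  write_genes_bed12(sim$genes, sim$exons, paths[["bed12"]])
  write.table(sim$cgi, paths[["cgi"]], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(paths)
}

write_genes_gtf <- function(genes, exons, path) {
  gl <- sprintf('%s\tmethvar\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_biotype "%s";',
                genes$chrom, genes$start + 1L, genes$end, genes$strand,
                genes$gene_id, genes$biotype)
  strand <- genes$strand[match(exons$gene_id, genes$gene_id)]
  bt <- genes$biotype[match(exons$gene_id, genes$gene_id)]
  el <- sprintf('%s\tmethvar\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_biotype "%s"; exon_id "%s"; exon_number "%d";',
                exons$chrom, exons$start + 1L, exons$end, strand,
                exons$gene_id, bt, exons$exon_id, exons$rank)
  writeLines(c(gl, el), path)
}

write_genes_bed12 <- function(genes, exons, path) {
  rows <- vapply(seq_len(nrow(genes)), function(i) {
    ex <- exons[exons$gene_id == genes$gene_id[i], , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    paste(genes$chrom[i], genes$start[i], genes$end[i], genes$gene_id[i], 0,
          genes$strand[i], genes$start[i], genes$end[i], "0",
          nrow(ex), paste0(ex$end - ex$start, collapse = ","),
          paste0(ex$start - genes$start[i], collapse = ","), sep = "\t")
  }, character(1))
  writeLines(rows, path)
}
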