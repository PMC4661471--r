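#' Read per-CpG bisulfite methylation calls
#'
#' Reads the four-column tab-separated call dialect: `chrom`,
#' `pos` (1-based position of the CpG cytosine), `meth_count`,
#' `unmeth_count`, no header.  Positions are converted to 0-based;
#' duplicate positions (e.g. strand-split callers reporting both strands of
#' a dyad) are summed; output is sorted by chromosome and position.
#'
#' @param path Path to the TSV file.
#' @return data.frame `chrom`, `pos` (0-based), `meth`, `unmeth`.
#' @export
read_cpg_calls <- function(path) {
  if (file.size(path) == 0L)
    return(data.frame(chrom = character(), pos = integer(),
                      meth = integer(), unmeth = integer()))
  x <- read.table(path, sep = "\t", header = FALSE,
                  colClasses = c("character", "integer", "integer", "integer"),
                  col.names = c("chrom", "pos", "meth", "unmeth"))
  bad <- !complete.cases(x)
  if (any(bad))
    stop("malformed call row at line ", which(bad)[1L], " of ", path)
  if (any(x$meth < 0 | x$unmeth < 0))
    stop("negative counts at line ", which(x$meth < 0 | x$unmeth < 0)[1L],
         " of ", path)
  x$pos <- x$pos - 1L
  key <- paste(x$chrom, x$pos)
  if (anyDuplicated(key)) {
    m <- rowsum(cbind(x$meth, x$unmeth), key, reorder = FALSE)
    first <- !duplicated(key)
    x <- data.frame(chrom = x$chrom[first], pos = x$pos[first],
                    meth = m[, 1L], unmeth = m[, 2L],
                    stringsAsFactors = FALSE)
  }
  x <- x[order(x$chrom, x$pos), , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' Convert six-column coverage files to the call dialect
#'
#' Accepts the common coverage dialect `chrom, start_1based, end, pct,
#' meth, unmeth` and returns the same data.frame as [read_cpg_calls()].
#'
#' @param path Path to the coverage file.
#' @return data.frame `chrom`, `pos` (0-based), `meth`, `unmeth`.
#' @export
read_coverage6 <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE,
                  col.names = c("chrom", "start", "end", "pct", "meth", "unmeth"))
  out <- data.frame(chrom = as.character(x$chrom), pos = x$start - 1L,
                    meth = x$meth, unmeth = x$unmeth, stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Write and read fragment BED4 files
#'
#' Fragments travel as BED4 (`chrom`, `start`, `end`, `fragment_id`),
#' 0-based half-open, matching the package's internal convention.
#'
#' @param fragments Fragment data.frame.
#' @param path File path.
#' @return `read_fragments_bed()` returns the fragment data.frame with a
#'   recomputed `length` column.
#' @export
write_fragments_bed <- function(fragments, path) {
  write.table(fragments[, c("chrom", "start", "end", "fragment_id")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_fragments_bed
#' @export
read_fragments_bed <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE,
                  col.names = c("chrom", "start", "end", "fragment_id"),
                  colClasses = c("character", "integer", "integer", "character"))
  x$length <- x$end - x$start
  x[, c("fragment_id", "chrom", "start", "end", "length")]
}

#' Read BED intervals
#'
#' Reads the first three columns of a BED file into the package's 0-based
#' half-open interval data.frame.
#'
#' @param path Path to the BED file.
#' @return data.frame `chrom`, `start`, `end`.
#' @export
read_bed_intervals <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE)[, 1:3]
  names(x) <- c("chrom", "start", "end")
  x$chrom <- as.character(x$chrom)
  x
}

#' Read gene models from GTF
#'
#' Imports `gene` and `exon` features and returns the package's gene and
#' exon tables (0-based half-open, TSS at the strand-aware 5' end).  Genes
#' lacking exon features get their full span as a single exon.
#'
#' @param path Path to the GTF file.
#' @return list with elements `genes` and `exons`.
#' @export
read_genes_gtf <- function(path) {
  g <- rtracklayer::import(path, format = "gtf")
  gd <- as.data.frame(g)
  if (is.null(gd$gene_biotype)) gd$gene_biotype <- "protein_coding"
  gg <- gd[gd$type == "gene", , drop = FALSE]
  genes <- data.frame(gene_id = gg$gene_id, chrom = as.character(gg$seqnames),
                      start = gg$start - 1L, end = gg$end,
                      strand = as.character(gg$strand),
                      biotype = gg$gene_biotype, stringsAsFactors = FALSE)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  ee <- gd[gd$type == "exon", , drop = FALSE]
  if (nrow(ee)) {
    exons <- data.frame(gene_id = ee$gene_id,
                        exon_id = if (!is.null(ee$exon_id)) ee$exon_id else
                          paste0(ee$gene_id, "_E", seq_len(nrow(ee))),
                        chrom = as.character(ee$seqnames),
                        start = ee$start - 1L, end = ee$end,
                        rank = if (!is.null(ee$exon_number))
                          as.integer(ee$exon_number) else NA_integer_,
                        stringsAsFactors = FALSE)
  } else {
    exons <- data.frame(gene_id = genes$gene_id,
                        exon_id = paste0(genes$gene_id, "_E1"),
                        chrom = genes$chrom, start = genes$start,
                        end = genes$end, rank = 1L, stringsAsFactors = FALSE)
  }
  if (anyNA(exons$rank)) {
    exons <- exons[order(exons$gene_id, exons$start), , drop = FALSE]
    str_by_gene <- genes$strand[match(exons$gene_id, genes$gene_id)]
    exons$rank <- stats::ave(seq_len(nrow(exons)), exons$gene_id,
                             FUN = seq_along)
    rev_rank <- stats::ave(seq_len(nrow(exons)), exons$gene_id,
                           FUN = function(i) rev(seq_along(i)))
    exons$rank[str_by_gene == "-"] <- rev_rank[str_by_gene == "-"]
  }
  list(genes = genes, exons = exons)
}

#' Read gene models from BED12
#'
#' @param path Path to a BED12 file (one transcript/gene per line).
#' @return list with elements `genes` and `exons`, as [read_genes_gtf()].
#' @export
read_genes_bed12 <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = x[[4]], chrom = x[[1]], start = x[[2]],
                      end = x[[3]], strand = x[[6]],
                      biotype = "protein_coding", stringsAsFactors = FALSE)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  exons <- do.call(rbind, lapply(seq_len(nrow(x)), function(i) {
    sizes <- as.integer(strsplit(x[[11]][i], ",")[[1L]])
    offs <- as.integer(strsplit(x[[12]][i], ",")[[1L]])
    st <- x[[2]][i] + offs
    ord <- if (x[[6]][i] == "+") seq_along(st) else rev(seq_along(st))
    data.frame(gene_id = x[[4]][i],
               exon_id = sprintf("%s_E%d", x[[4]][i], ord),
               chrom = x[[1]][i], start = st, end = st + sizes,
               rank = ord, stringsAsFactors = FALSE)
  }))
  list(genes = genes, exons = exons)
}
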