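#' In silico MspI digestion of a single chromosome
#'
#' MspI cuts at C^CGG.  For every occurrence of the CCGG motif starting at
#' 0-based offset `i`, a cut is placed between `i` and `i + 1`.  Internal
#' fragments (cut at both ends) span successive cut positions; the terminal
#' chromosome stubs are excluded because real RRBS libraries only contain
#' doubly cut fragments.  Each internal fragment therefore begins with CGG
#' and ends with C.
#'
#' @param sequence A single chromosome sequence: a character scalar or a
#'   [Biostrings::DNAString].  Case-insensitive; `N` runs never match.
#'   Ambiguity codes other than `A/C/G/T/N` are rejected.
#' @param chrom Chromosome name recorded in the output.
#' @return A data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `length`.  Zero rows when the sequence has fewer than two
#'   CCGG sites.  The 0-based cut offsets (position of each CCGG `i`, the
#'   cut lying at `i + 1`) are attached as attribute `"cuts"`.
#' @examples
#' digest_sequence("AAACCGGTTTTCCGGAAA")  # one fragment [4, 12)
#' @export
digest_sequence <- function(sequence, chrom = "chr1") {
  seq_chr <- toupper(as.character(sequence))
  if (length(seq_chr) != 1L) stop("'sequence' must be a single chromosome")
  if (nzchar(seq_chr) && grepl("[^ACGTN]", seq_chr))
    stop("sequence contains ambiguity codes other than N")
  if (!nzchar(seq_chr)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), length = integer())
    attr(out, "cuts") <- integer()
    return(out)
  }
  hits <- Biostrings::matchPattern("CCGG", Biostrings::DNAString(seq_chr))
  sites <- BiocGenerics::start(hits) - 1L   # 0-based motif offsets
  if (length(sites) < 2L) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), length = integer())
    attr(out, "cuts") <- sites
    return(out)
  }
  cuts <- sites + 1L                        # cut between i and i+1
  start <- cuts[-length(cuts)]
  end <- cuts[-1L]
  out <- data.frame(chrom = chrom, start = start, end = end,
                    length = end - start, stringsAsFactors = FALSE)
  attr(out, "cuts") <- sites
  out
}

#' Digest a whole genome into MspI fragments
#'
#' Applies [digest_sequence()] to every chromosome and assigns stable
#' fragment identifiers `<chrom>_F<index>` in genomic order.
#'
#' @param genome A named character vector or [Biostrings::DNAStringSet] of
#'   chromosome sequences.
#' @return Fragment data.frame (`fragment_id`, `chrom`, `start`, `end`,
#'   `length`), 0-based half-open, ordered within each chromosome.
#' @export
digest_genome <- function(genome) {
  if (is(genome, "DNAStringSet")) genome <- as.character(genome)
  if (is.null(names(genome))) stop("genome sequences must be named")
  frags <- lapply(names(genome), function(ch) digest_sequence(genome[[ch]], ch))
  out <- do.call(rbind, lapply(frags, function(f) { attr(f, "cuts") <- NULL; f }))
  if (is.null(out) || nrow(out) == 0L)
    return(data.frame(fragment_id = character(), chrom = character(),
                      start = integer(), end = integer(), length = integer()))
  out$fragment_id <- paste0(out$chrom, "_F", stats::ave(out$start, out$chrom,
                                                        FUN = seq_along))
  rownames(out) <- NULL
  out[, c("fragment_id", "chrom", "start", "end", "length")]
}

#' Size-select the reduced-representation fragment universe
#'
#' Keeps fragments whose length lies in `[min_len, max_len]` (both bounds
#' inclusive), the size window captured by RRBS library preparation.
#'
#' @param fragments Fragment data.frame from [digest_genome()].
#' @param min_len,max_len Inclusive length bounds in bp (defaults 40 and
#'   220).
#' @return The selected fragments, with a `"summary"` attribute holding the
#'   count, median and mean length.
#' @export
select_rr_fragments <- function(fragments, min_len = 40L, max_len = 220L) {
  if (min_len > max_len) stop("min_len must not exceed max_len")
  keep <- fragments$length >= min_len & fragments$length <= max_len
  out <- fragments[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "summary") <- c(n = nrow(out),
                            median_length = if (nrow(out)) median(out$length) else NA_real_,
                            mean_length = if (nrow(out)) mean(out$length) else NA_real_)
  out
}

#' Locate CpG sites within fragments
#'
#' Finds the 0-based position of the C of every CG dinucleotide on the
#' forward strand inside each fragment.  Reverse-strand calls must be
#' collapsed to the forward-strand C of the dyad by the call reader.  Every
#' MspI internal fragment starts with CGG, so its first base always opens a
#' CpG.
#'
#' @param fragments Fragment data.frame (0-based half-open intervals).
#' @param genome Named character vector or [Biostrings::DNAStringSet].
#' @return data.frame with columns `fragment_id`, `chrom`, `pos` (0-based
#'   position of the dyad C), one row per CpG.
#' @export
locate_cpgs <- function(fragments, genome) {
  if (is(genome, "DNAStringSet")) genome <- as.character(genome)
  bad <- !(fragments$chrom %in% names(genome))
  if (any(bad)) stop("fragment chromosome absent from genome: ",
                     fragments$chrom[which(bad)[1L]])
  res <- vector("list", nrow(fragments))
  for (i in seq_len(nrow(fragments))) {
    ch <- fragments$chrom[i]
    if (fragments$start[i] < 0L || fragments$end[i] > nchar(genome[[ch]]))
      stop("fragment interval out of genome bounds: ", fragments$fragment_id[i])
    sub <- toupper(substr(genome[[ch]], fragments$start[i] + 1L, fragments$end[i]))
    off <- gregexpr("CG", sub, fixed = TRUE)[[1L]]
    off <- off[off > 0L]
    if (length(off))
      res[[i]] <- data.frame(fragment_id = fragments$fragment_id[i], chrom = ch,
                             pos = fragments$start[i] + off - 1L,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(fragment_id = character(), chrom = character(),
                      pos = integer())
  rownames(out) <- NULL
  out
}
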