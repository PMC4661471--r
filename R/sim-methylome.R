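#' Simulate per-individual CpG methylation calls with planted truth
#'
#' Generates bisulfite call files for a cohort over the RR fragments of a
#' synthetic genome under a beta-binomial model.  Each fragment gets a
#' methylation mode (unmethylated ~3% or methylated ~88%, mixture weights
#' from the configuration), reproducing the bimodal methylation
#' distribution of a homogeneous cell type.  A planted subset of autosomal
#' fragments is "variable": their per-individual true methylation is drawn
#' from a Beta distribution with an intermediate mean (uniform on 20-80%)
#' and low concentration `dispersion_variable`; all other fragments use the
#' tight concentration `dispersion_null` (`Inf` collapses the Beta to its
#' mean, giving pure binomial counts - the calibration null).  Read counts
#' are binomial given the individual's true methylation, with per-CpG
#' coverage drawn from a negative binomial around `coverage_mean`.
#'
#' When the genome carries a pseudo-X chromosome and `config$sexes` is set,
#' a fraction `frac_sex_diff` of chrX fragments is made sex-differential
#' (females ~75%, males ~15% methylated), emulating X inactivation.
#'
#' Randomness is split into streams: fragment-level truth uses the global
#' seed, and individual `j` draws from a sub-seed derived from `(seed, j)`,
#' so enlarging the cohort never changes the data of existing individuals.
#'
#' @param sim A `"sim_genome"` object, or a list with elements `fragments`
#'   (RR fragment data.frame) and `cpgs` (from [locate_cpgs()]); the genome
#'   is digested and size-selected internally when a `"sim_genome"` is
#'   given.
#' @param config A [sim_config()]; defaults to `sim$config`.
#' @return A list of class `"sim_methylome"`: `calls` (named list of
#'   per-individual call data.frames in the [read_cpg_calls()] dialect,
#'   0-based positions), `truth` (fragment_id, is_variable, is_sex_diff,
#'   linked_exon, true methylation % per individual), `fragments` (with
#'   `n_cpgs`), `cpgs`, `individuals`, `config`.
#' @export
simulate_methylome <- function(sim, config = sim$config) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(sim, "sim_genome")) {
    frags <- select_rr_fragments(digest_genome(sim$genome))
    cpgs <- locate_cpgs(frags, sim$genome)
    exons <- sim$exons
  } else {
    frags <- sim$fragments; cpgs <- sim$cpgs; exons <- sim$exons
  }
  zero <- !(frags$fragment_id %in% cpgs$fragment_id)
  if (any(zero)) {
    warning(sum(zero), " fragment(s) without CpG sites skipped")
    frags <- frags[!zero, , drop = FALSE]
  }
  frags$n_cpgs <- as.integer(table(cpgs$fragment_id)[frags$fragment_id])
  n <- nrow(frags)
  individuals <- paste0("S", seq_len(config$n_individuals))

  # fragment-level truth (global seed stream).  Fragments in promoters
  # (within 1 kb of a TSS) or CGI cores are drawn from the unmethylated
  # mode with high probability, as in real methylomes; elsewhere the
  # configured mixture weight applies.
  set.seed(config$seed + 1L)
  p_low <- rep(config$base_meth_profile[["low"]], n)
  if (inherits(sim, "sim_genome")) {
    mid <- (frags$start + frags$end) %/% 2L
    regul <- rep(FALSE, n)
    for (i in seq_len(n)) {
      tssd <- abs(sim$genes$tss[sim$genes$chrom == frags$chrom[i]] - mid[i])
      cg <- sim$cgi[sim$cgi$chrom == frags$chrom[i], , drop = FALSE]
      in_cgi <- any(cg$start <= mid[i] & mid[i] < cg$end)
      regul[i] <- in_cgi || (length(tssd) && min(tssd) <= 1000L)
    }
    p_low[regul] <- 0.8
  }
  mode_low <- runif(n) < p_low
  mean_f <- ifelse(mode_low, config$meth_modes[["low"]],
                   config$meth_modes[["high"]])
  mean_f <- pmin(pmax(mean_f + runif(n, -0.02, 0.02), 0.005), 0.995)
  autosomal <- frags$chrom != "chrX"
  n_var <- round(config$frac_variable * sum(autosomal))
  is_variable <- rep(FALSE, n)
  if (n_var > 0L)
    is_variable[sample(which(autosomal), n_var)] <- TRUE
  mean_f[is_variable] <- runif(sum(is_variable), 0.2, 0.8)
  conc <- ifelse(is_variable, config$dispersion_variable, config$dispersion_null)

  is_sex_diff <- rep(FALSE, n)
  if (!is.null(config$sexes) && any(frags$chrom == "chrX")) {
    xi <- which(frags$chrom == "chrX")
    is_sex_diff[sample(xi, round(config$frac_sex_diff * length(xi)))] <- TRUE
  }

  # linked exons: variable fragments overlapping an exon
  linked <- rep(NA_character_, n)
  if (!is.null(exons) && any(is_variable)) {
    for (i in which(is_variable)) {
      hit <- which(exons$chrom == frags$chrom[i] &
                     exons$start < frags$end[i] & exons$end > frags$start[i])
      if (length(hit)) {
        w <- pmin(exons$end[hit], frags$end[i]) - pmax(exons$start[hit], frags$start[i])
        linked[i] <- exons$exon_id[hit[which.max(w)]]
      }
    }
  }

  cpg_idx <- match(cpgs$fragment_id, frags$fragment_id)
  truth_meth <- matrix(NA_real_, n, config$n_individuals,
                       dimnames = list(frags$fragment_id, individuals))
  calls <- vector("list", config$n_individuals)
  names(calls) <- individuals
  for (j in seq_len(config$n_individuals)) {
    set.seed(individual_seed(config$seed, j))
    mu <- mean_f
    if (any(is_sex_diff))
      mu[is_sex_diff] <- if (config$sexes[j] == "F") 0.75 else 0.15
    p <- ifelse(is.finite(conc),
                rbeta(n, mu * conc, (1 - mu) * conc), mu)
    # guard against degenerate beta draws at machine 0/1
    p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
    truth_meth[, j] <- 100 * p
    cov <- rnbinom(nrow(cpgs), mu = config$coverage_mean,
                   size = config$coverage_size)
    m <- rbinom(nrow(cpgs), cov, p[cpg_idx])
    keep <- cov > 0L
    calls[[j]] <- data.frame(chrom = cpgs$chrom[keep], pos = cpgs$pos[keep],
                             meth = m[keep], unmeth = cov[keep] - m[keep],
                             stringsAsFactors = FALSE)
  }
  truth <- data.frame(fragment_id = frags$fragment_id,
                      is_variable = is_variable, is_sex_diff = is_sex_diff,
                      linked_exon = linked, stringsAsFactors = FALSE)
  truth <- cbind(truth, as.data.frame(truth_meth))
  structure(list(calls = calls, truth = truth, fragments = frags,
                 cpgs = cpgs, individuals = individuals, config = config),
            class = "sim_methylome")
}

#' @export
print.sim_methylome <- function(x, ...) {
  cat(sprintf("Synthetic methylome: %d individuals, %d RR fragments (%d planted variable, %d sex-differential)\n",
              length(x$individuals), nrow(x$fragments),
              sum(x$truth$is_variable), sum(x$truth$is_sex_diff)))
  invisible(x)
}

#' Write synthetic methylome call files
#'
#' Writes one call TSV per individual (`calls_<id>.tsv`, 1-based positions,
#' the [read_cpg_calls()] dialect), the RR fragment BED and the truth
#' table.
#'
#' @param sim A `"sim_methylome"` object.
#' @param outdir Output directory.
#' @return Invisibly, the list of file paths (`calls`, `fragments`,
#'   `truth`).
#' @export
write_methylome_files <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- lapply(sim$individuals, function(id) {
    p <- file.path(outdir, paste0("calls_", id, ".tsv"))
    x <- sim$calls[[id]]
    write.table(data.frame(x$chrom, x$pos + 1L, x$meth, x$unmeth), p,
                sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    p
  })
  names(paths) <- sim$individuals
  fp <- file.path(outdir, "rr_fragments.bed")
  write_fragments_bed(sim$fragments, fp)
  tp <- file.path(outdir, "truth.tsv")
  write.table(sim$truth, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(calls = paths, fragments = fp, truth = tp))
}

#' Simulate fragment-level methylation counts directly
#'
#' A fast path to cohort count matrices that skips genome construction:
#' fragments are abstract units with a CpG count drawn uniformly from
#' `cpg_range`, and counts follow the same beta-binomial model as
#' [simulate_methylome()].  Intended for calibration and power studies of
#' the chi-square caller at large fragment numbers.
#'
#' @param n_fragments Number of fragments.
#' @param config A [sim_config()]; `frac_variable`, dispersions, coverage
#'   and cohort size are taken from it.
#' @param cpg_range Integer range of CpGs per fragment.
#' @param min_cpgs,min_reads,min_individuals Qualification parameters
#'   passed to the cohort constructor.
#' @return A `"meth_cohort"` (see [assemble_cohort()]) whose `truth`
#'   element carries the planted `is_variable` flags and true per-individual
#'   methylation percentages.
#' @export
simulate_fragment_counts <- function(n_fragments, config,
                                     cpg_range = c(3L, 10L),
                                     min_cpgs = 2L, min_reads = 10L,
                                     min_individuals = NULL) {
  stopifnot(inherits(config, "sim_config"))
  k <- config$n_individuals
  if (is.null(min_individuals)) min_individuals <- max(2L, k - 2L)
  set.seed(config$seed + 1L)
  ncpg <- sample(seq(cpg_range[1L], cpg_range[2L]), n_fragments, replace = TRUE)
  mode_low <- runif(n_fragments) < config$base_meth_profile[["low"]]
  mean_f <- ifelse(mode_low, config$meth_modes[["low"]],
                   config$meth_modes[["high"]])
  n_var <- round(config$frac_variable * n_fragments)
  is_variable <- rep(FALSE, n_fragments)
  if (n_var > 0L) is_variable[sample.int(n_fragments, n_var)] <- TRUE
  mean_f[is_variable] <- runif(sum(is_variable), 0.2, 0.8)
  conc <- ifelse(is_variable, config$dispersion_variable, config$dispersion_null)

  ids <- sprintf("F%06d", seq_len(n_fragments))
  individuals <- paste0("S", seq_len(k))
  M <- U <- CC <- matrix(0L, n_fragments, k, dimnames = list(ids, individuals))
  truth_meth <- matrix(NA_real_, n_fragments, k, dimnames = list(ids, individuals))
  for (j in seq_len(k)) {
    set.seed(individual_seed(config$seed, j))
    p <- ifelse(is.finite(conc), rbeta(n_fragments, mean_f * conc,
                                       (1 - mean_f) * conc), mean_f)
    p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
    truth_meth[, j] <- 100 * p
    cov <- matrix(rnbinom(n_fragments * max(ncpg), mu = config$coverage_mean,
                          size = config$coverage_size),
                  n_fragments, max(ncpg))
    cov[col(cov) > ncpg] <- 0L
    tot <- rowSums(cov)
    M[, j] <- rbinom(n_fragments, tot, p)
    U[, j] <- tot - M[, j]
    CC[, j] <- rowSums(cov >= min_reads)
  }
  frags <- data.frame(fragment_id = ids, chrom = "chr1",
                      start = (seq_len(n_fragments) - 1L) * 1000L,
                      end = (seq_len(n_fragments) - 1L) * 1000L + 100L,
                      length = 100L, n_cpgs = ncpg, stringsAsFactors = FALSE)
  truth <- data.frame(fragment_id = ids, is_variable = is_variable,
                      stringsAsFactors = FALSE)
  truth <- cbind(truth, as.data.frame(truth_meth))
  ch <- new_meth_cohort(M, U, CC, frags, individuals,
                        min_individuals = min_individuals,
                        min_cpgs = min_cpgs, min_reads = min_reads,
                        mode = "per_cpg")
  ch$truth <- truth
  ch
}
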