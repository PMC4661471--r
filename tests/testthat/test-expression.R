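test_that("methylation bins use closed-left-upper edges and partition input", {
  m <- c(0, 15, 30, 30.1, 70, 70.1, 100)
  b <- cut(m, c(0, 30, 70, 100), include.lowest = TRUE, right = TRUE)
  expect_equal(as.character(b[3]), "[0,30]")   # boundary 30 -> lower bin
  expect_equal(as.character(b[5]), "(30,70]")
  set.seed(61)
  meth <- runif(90, 0, 100)
  res <- methylation_expression_bins(meth, rexp(90, 0.1))
  expect_equal(sum(res$bins$n), 90L)
})

test_that("bin ANOVA detects planted inverse coupling and not its absence", {
  set.seed(62)
  n <- 300
  meth <- runif(n, 0, 100)
  # inverse coupling on the log scale
  ab <- exp(4 - 2.5 * meth / 100 + rnorm(n, 0, 0.4))
  res <- methylation_expression_bins(meth, ab)
  expect_lt(res$anova_p, 0.05)
  low <- res$bins$mean_log[res$bins$bin == "[0,30]"]
  high <- res$bins$mean_log[res$bins$bin == "(70,100]"]
  expect_gt(low, high)
  expect_true(all(nchar(res$bins$letter) >= 1))
  # low and high bins must not share a letter
  expect_false(grepl(res$bins$letter[res$bins$bin == "[0,30]"],
                     res$bins$letter[res$bins$bin == "(70,100]"], fixed = TRUE))

  # uncoupled abundance: no systematic bin separation
  res0 <- methylation_expression_bins(meth, rexp(n, 0.1))
  expect_gt(res0$anova_p, 0.001)

  # sparse bin handling
  expect_warning(methylation_expression_bins(c(1, 2, 3, 50, 80, 81, 82),
                                             rexp(7)), "dropped")
})

test_that("TSS-window association finds the coupled window, strand-aware", {
  w <- small_world()
  es <- simulate_expression(w$gs, w$ms)   # coupling in downstream 0-500
  P <- methylation_matrix(w$cohort)
  tw <- tss_window_association(w$fit$results, P, w$gs$genes,
                               es$gene_abundance)
  expect_true("down_0_500" %in% tw$window)
  best <- tw$window[which.min(tw$anova_p)]
  expect_equal(best, "down_0_500")

  # minus-strand genes: the downstream window lies below the TSS
  g <- w$gs$genes[w$gs$genes$strand == "-" &
                    w$gs$genes$biotype == "protein_coding", ][1, ]
  fr <- data.frame(fragment_id = "fx", chrom = g$chrom,
                   start = g$tss - 300L, end = g$tss - 200L)
  inds <- paste0("S", 1:5)
  meth1 <- matrix(c(5, 20, 50, 80, 95), 1, 5, dimnames = list("fx", inds))
  ab <- data.frame(gene_id = g$gene_id, individual_id = inds,
                   abundance = 1:5)
  tw2 <- tss_window_association(fr, meth1, w$gs$genes, ab,
                                windows = list(down_0_500 = c(-500, 0)))
  expect_equal(nrow(tw2), 1L)   # assigned to the downstream window
})

test_that("exon correlations follow exact linear cases and the Fisher band", {
  em <- data.frame(exon_id = paste0("e", 1:6), gene_id = "g",
                   individual_id = "S1", meth_pct = seq(10, 60, 10))
  ec_up <- data.frame(exon_id = paste0("e", 1:6), individual_id = "S1",
                      count = 2^(seq(2, 7)) - 1)
  r <- exon_methylation_correlation(em, ec_up)
  expect_equal(r$pooled$r, 1)
  ec_dn <- data.frame(exon_id = paste0("e", 1:6), individual_id = "S1",
                      count = 2^(seq(7, 2)) - 1)
  expect_equal(exon_methylation_correlation(em, ec_dn)$pooled$r, -1)
  # zero variance sentinel
  em0 <- em; em0$meth_pct <- 50
  expect_true(is.na(exon_methylation_correlation(em0, ec_up)$pooled$r))

  # coupling 0.7 at 200 pairs: r inside the analytic Fisher-z band
  set.seed(63)
  n <- 200
  z <- rnorm(n)
  meth <- 50 + 20 * z
  y <- 0.7 * z + sqrt(1 - 0.49) * rnorm(n)
  cnt <- round(2^(8 + 2 * y))
  emr <- data.frame(exon_id = paste0("e", 1:n), gene_id = "g",
                    individual_id = "S1", meth_pct = meth)
  ecr <- data.frame(exon_id = paste0("e", 1:n), individual_id = "S1",
                    count = cnt)
  r2 <- exon_methylation_correlation(emr, ecr)$pooled$r
  band <- tanh(atanh(0.7) + c(-3, 3) / sqrt(n - 3))
  expect_gt(r2, band[1])
  expect_lt(r2, band[2])
})

test_that("iVMF exon-inclusion shows a local effect with adjacent-exon controls", {
  w <- small_world()
  es <- simulate_expression(w$gs, w$ms)
  P <- methylation_matrix(w$cohort)
  iv <- call_ivmfs(w$fit)
  inc <- ivmf_exon_inclusion(iv, P, w$gs$exons, es$exon_counts)
  expect_gt(inc$overlap$n, 30)
  expect_gt(inc$overlap$r, inc$upstream$r)
  expect_gt(inc$overlap$r, inc$downstream$r)
  expect_lt(inc$overlap$p, 1e-6)

  # no overlapping differential exons: empty result, not an error
  ec0 <- es$exon_counts; ec0$is_differential <- FALSE
  inc0 <- ivmf_exon_inclusion(iv, P, w$gs$exons, ec0)
  expect_equal(inc0$overlap$n, 0L)
  expect_true(is.na(inc0$overlap$r))
})

test_that("single-exon genes lose the controls but keep the overlap correlation", {
  ex1 <- data.frame(gene_id = "g1", exon_id = "g1_E1", chrom = "chr1",
                    start = 100L, end = 500L, rank = 1L)
  fr <- data.frame(fragment_id = "fv", chrom = "chr1", start = 150L,
                   end = 250L)
  meth <- matrix(c(10, 50, 90, 30), 1, 4,
                 dimnames = list("fv", paste0("S", 1:4)))
  cnt <- data.frame(exon_id = "g1_E1", individual_id = paste0("S", 1:4),
                    count = c(4, 60, 900, 25), is_differential = TRUE)
  inc <- ivmf_exon_inclusion(fr, meth, ex1, cnt)
  expect_gt(inc$overlap$r, 0.9)
  expect_equal(inc$upstream$n, 0L)
  expect_equal(inc$downstream$n, 0L)
})

test_that("uniform coupling across a gene removes the local contrast", {
  # couple all three exons of each gene to the same latent methylation
  set.seed(64)
  n_genes <- 40; k <- 6
  exons <- do.call(rbind, lapply(seq_len(n_genes), function(g)
    data.frame(gene_id = paste0("g", g),
               exon_id = paste0("g", g, "_E", 1:3), chrom = "chr1",
               start = g * 10000L + c(0L, 1300L, 2600L),
               end = g * 10000L + c(400L, 1700L, 3000L), rank = 1:3)))
  frs <- data.frame(fragment_id = paste0("f", seq_len(n_genes)),
                    chrom = "chr1", start = seq_len(n_genes) * 10000L + 1400L,
                    end = seq_len(n_genes) * 10000L + 1500L)
  meth <- matrix(runif(n_genes * k, 0, 100), n_genes, k,
                 dimnames = list(frs$fragment_id, paste0("S", 1:k)))
  z <- scale(as.vector(meth))[, 1]
  rows <- expand.grid(exon = 1:3, gene = seq_len(n_genes), ind = 1:k)
  cnt <- data.frame(
    exon_id = paste0("g", rows$gene, "_E", rows$exon),
    individual_id = paste0("S", rows$ind),
    count = round(2^(8 + 2 * (0.7 * z[(rows$ind - 1L) * n_genes + rows$gene] +
                                sqrt(0.51) * rnorm(nrow(rows))))),
    is_differential = rows$exon == 2L)
  inc <- ivmf_exon_inclusion(frs, meth, exons, cnt)
  expect_gt(inc$overlap$n, 100)
  rs <- c(inc$overlap$r, inc$upstream$r, inc$downstream$r)
  expect_lt(max(rs) - min(rs), 0.2)
  expect_true(all(rs > 0.4))
})
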