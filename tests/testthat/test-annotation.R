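# one + strand gene [10000, 13000) with exons at 10000, 11300, 12600 (400 bp),
# and one - strand gene [30000, 33000) (TSS at 32999)
toy_genes <- data.frame(
  gene_id = c("gA", "gB"), chrom = "chr1",
  start = c(10000L, 30000L), end = c(13000L, 33000L),
  strand = c("+", "-"), biotype = "protein_coding",
  tss = c(10000L, 32999L), stringsAsFactors = FALSE)
toy_exons <- data.frame(
  gene_id = rep(c("gA", "gB"), each = 3),
  exon_id = c("gA_E1", "gA_E2", "gA_E3", "gB_E3", "gB_E2", "gB_E1"),
  chrom = "chr1",
  start = c(10000L, 11300L, 12600L, 30000L, 31300L, 32600L),
  end = c(10400L, 11700L, 13000L, 30400L, 31700L, 33000L),
  rank = c(1L, 2L, 3L, 3L, 2L, 1L), stringsAsFactors = FALSE)

frag_at <- function(start, end, id = "f") {
  data.frame(fragment_id = id, chrom = "chr1", start = as.integer(start),
             end = as.integer(end), stringsAsFactors = FALSE)
}

ctx <- function(start, end) {
  classify_gene_context(frag_at(start, end), toy_genes, toy_exons)
}

test_that("gene context covers promoter bins, gene body and distant classes", {
  expect_equal(ctx(8950, 9050)$category, "promoter_0_2kb")   # 1 kb upstream
  expect_equal(ctx(6950, 7050)$category, "promoter_2_5kb")
  expect_equal(ctx(3950, 4050)$category, "upstream_5_10kb")
  # fragment on the far side, 12 kb upstream of gB's TSS (- strand)
  far <- classify_gene_context(frag_at(44950, 45050),
                               toy_genes, toy_exons)
  expect_equal(far$category, "distant_gt10kb")
  expect_equal(far$gene_id, "gB")
  expect_equal(ctx(9990, 10050)$category, "tss_overlap")
  expect_equal(ctx(10100, 10200)$category, "exon")
  expect_equal(ctx(10600, 10700)$category, "intron")
  # spans exon end (10400) into the intron, transcription direction +
  expect_equal(ctx(10350, 10450)$category, "exon_intron_boundary")
  # enters exon 2 from the upstream intron
  expect_equal(ctx(11250, 11350)$category, "intron_exon_boundary")
  # on the - strand gene transcription runs right to left: a fragment
  # spanning an exon's genomic end enters it from the preceding intron
  expect_equal(ctx(30350, 30450)$category, "intron_exon_boundary")
  expect_equal(ctx(31650, 31750)$category, "intron_exon_boundary")
  expect_equal(ctx(31250, 31350)$category, "exon_intron_boundary")
})

test_that("nearest-gene assignment uses strand-aware TSS distance", {
  a <- ctx(8950, 9050)
  expect_equal(a$gene_id, "gA")
  expect_equal(a$distance_to_tss, 10000 - 9049)
  # upstream of the - strand gene means larger coordinates
  b <- classify_gene_context(frag_at(33950, 34050), toy_genes, toy_exons)
  expect_equal(b$gene_id, "gB")
  expect_equal(b$category, "promoter_0_2kb")
  expect_equal(b$distance_to_tss, 33950 - 32999)
})

test_that("gene context is strand-symmetric under genome mirroring", {
  L <- 50000L
  mirror_iv <- function(s, e) c(L - e, L - s)
  mg <- toy_genes
  mg$strand <- ifelse(toy_genes$strand == "+", "-", "+")
  mg[, c("start", "end")] <- t(apply(toy_genes[, c("start", "end")], 1,
                                     function(x) mirror_iv(x[1], x[2])))
  mg$tss <- ifelse(mg$strand == "+", mg$start, mg$end - 1L)
  me <- toy_exons
  me[, c("start", "end")] <- t(apply(toy_exons[, c("start", "end")], 1,
                                     function(x) mirror_iv(x[1], x[2])))
  cases <- list(c(8950, 9050), c(10100, 10200), c(10350, 10450),
                c(11250, 11350), c(6950, 7050), c(3950, 4050))
  for (cs in cases) {
    orig <- ctx(cs[1], cs[2])$category
    m <- mirror_iv(cs[1], cs[2])
    mirr <- classify_gene_context(frag_at(m[1], m[2]), mg, me)$category
    expect_equal(mirr, orig)
  }
})

test_that("empty or non-coding gene sets give the unassigned sentinel", {
  nc <- toy_genes; nc$biotype <- "lincRNA"
  got <- classify_gene_context(frag_at(8950, 9050), nc, toy_exons)
  expect_equal(got$category, "unassigned")
  expect_true(is.na(got$gene_id))
})

test_that("equidistant genes are tie-broken lexicographically with a warning", {
  g2 <- toy_genes
  g2$gene_id <- c("gZ", "gB")
  g2$start <- c(20000L, 30000L); g2$end <- c(23000L, 33000L)
  g2$strand <- c("-", "+"); g2$tss <- c(22999L, 30000L)
  # dist to gZ = 25000 - 22999 = 2001; dist to gB = 30000 - 27999 = 2001
  fr <- frag_at(25000, 28000)
  expect_warning(got <- classify_gene_context(fr, g2, toy_exons[0, ]),
                 "equidistant")
  expect_equal(got$gene_id, "gB")
})

test_that("CGI classes follow the midpoint and 2 kb band arithmetic", {
  cgi <- data.frame(chrom = "chr1", start = 10000L, end = 11000L)
  frag_mid <- function(mid) frag_at(mid - 50L, mid + 50L)
  expect_equal(classify_cgi_context(frag_mid(10500), cgi), "core")
  expect_equal(classify_cgi_context(frag_mid(12000), cgi), "shore")  # 1 kb out
  expect_equal(classify_cgi_context(frag_mid(14000), cgi), "shelf")  # 3 kb out
  expect_equal(classify_cgi_context(frag_mid(16000), cgi), "none")   # 5 kb out
  expect_equal(classify_cgi_context(frag_mid(8500), cgi), "shore")   # left side
  # nearest island wins
  cgi2 <- rbind(cgi, data.frame(chrom = "chr1", start = 15000L, end = 15600L))
  expect_equal(classify_cgi_context(frag_mid(14800), cgi2), "shore")
  expect_equal(classify_cgi_context(frag_mid(15300), cgi2), "core")
})

test_that("context categories partition the assigned fragments", {
  w <- small_world()
  ann <- classify_gene_context(w$fit$results, w$gs$genes, w$gs$exons)
  expect_equal(nrow(ann), nrow(w$fit$results))
  expect_false(any(is.na(ann$category)))
  expect_equal(sum(table(ann$category)), nrow(ann))
  cgic <- classify_cgi_context(w$fit$results, w$gs$cgi)
  expect_equal(length(cgic), nrow(w$fit$results))
  # synthetic CGIs sit on promoters: core fragments should be CG-dense
  expect_gt(sum(cgic == "core"), 0)
})

test_that("variability scores and VMG calling follow the count and score gates", {
  vs <- variability_score(rep(TRUE, 5))
  expect_equal(vs$vs, 1)
  expect_equal(variability_score(rep(FALSE, 7))$vs, 0)
  expect_equal(round(variability_score(c(rep(TRUE, 9), rep(FALSE, 4)))$vs, 2),
               0.69)
  expect_error(variability_score(logical(0)), "at least one")

  scores <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                       n_analysed = c(6L, 2L, 22L, 10L),
                       n_ivmf = c(3L, 2L, 9L, 0L),
                       vs = c(0.5, 1.0, 0.409, 0))
  vmg <- call_vmgs(scores)
  expect_equal(vmg$gene_id, "g1")        # g2 fails the count gate at vs 1.0
  expect_true("g3" %in% scores$gene_id[scores$n_ivmf >= 3])  # listed, not top
  # vs is scale-free
  expect_equal(variability_score(c(rep(TRUE, 3), rep(FALSE, 3)))$vs,
               variability_score(c(rep(TRUE, 6), rep(FALSE, 6)))$vs)
})

test_that("per-gene scores aggregate analysed fragments and iVMFs", {
  w <- small_world()
  ann <- classify_gene_context(w$fit$results, w$gs$genes, w$gs$exons)
  sc <- gene_variability_scores(w$fit, ann)
  expect_true(all(sc$n_ivmf <= sc$n_analysed))
  expect_true(all(sc$vs >= 0 & sc$vs <= 1))
  expect_equal(sum(sc$n_ivmf),
               sum(w$fit$results$is_ivmf & w$fit$results$autosomal &
                     !is.na(ann$gene_id[match(w$fit$results$fragment_id,
                                              ann$fragment_id)])))
  # region restriction only shrinks the denominator
  sc_prom <- gene_variability_scores(w$fit, ann,
    categories = c("tss_overlap", "promoter_0_2kb", "promoter_2_5kb"))
  i <- match(sc_prom$gene_id, sc$gene_id)
  expect_true(all(sc_prom$n_analysed <= sc$n_analysed[i]))
})

test_that("feature methylation summary reports medians and an across-feature test", {
  s <- summarize_methylation_by_feature(c(rep(50, 6)),
                                        rep(c("a", "b"), each = 3))
  expect_true(all(s$medians == 50))
  expect_true(is.na(s$anova_p))  # zero variance sentinel
  s2 <- summarize_methylation_by_feature(c(0, 0, 0, 100, 100, 100) +
                                           c(0.1, -0.1, 0, 0.1, -0.1, 0),
                                         rep(c("a", "b"), each = 3))
  expect_gt(s2$anova_F, 1e4)
  # single-category input is a sentinel, not an error
  s3 <- summarize_methylation_by_feature(c(1, 2, 3), rep("a", 3))
  expect_true(is.na(s3$anova_p))
  # synthetic construction: promoter/CGI fragments are hypomethylated
  w <- small_world()
  cgic <- classify_cgi_context(w$fit$results, w$gs$cgi)
  s4 <- summarize_methylation_by_feature(w$fit$results$mean_pct, cgic)
  expect_lt(s4$medians[["core"]], s4$medians[["none"]])
  expect_lt(s4$anova_p, 0.05)
})
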