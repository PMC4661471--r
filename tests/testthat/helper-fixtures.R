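# Shared synthetic fixtures, built once per test run.
fixture_env <- new.env(parent = emptyenv())

small_world <- function() {
  if (is.null(fixture_env$world)) {
    cfg <- sim_config(seed = 42)
    gs <- simulate_genome(cfg)
    ms <- simulate_methylome(gs)
    tabs <- lapply(ms$calls, aggregate_fragment_methylation,
                   fragments = ms$fragments)
    ch <- assemble_cohort(tabs, ms$fragments, min_individuals = 9)
    fit <- ivmf_test(ch)
    fixture_env$world <- list(cfg = cfg, gs = gs, ms = ms, cohort = ch,
                              fit = fit)
  }
  fixture_env$world
}

# naive independent digestion oracle: scan for CCGG with a sliding window
naive_digest <- function(seq_chr) {
  seq_chr <- toupper(seq_chr)
  n <- nchar(seq_chr)
  sites <- integer(0)
  if (n >= 4) {
    for (i in 1:(n - 3)) {
      if (substr(seq_chr, i, i + 3) == "CCGG") sites <- c(sites, i - 1L)
    }
  }
  if (length(sites) < 2) return(data.frame(start = integer(), end = integer()))
  cuts <- sites + 1L
  data.frame(start = cuts[-length(cuts)], end = cuts[-1L])
}

random_dna <- function(n, p_ccgg = 0.02) {
  s <- sample(c("A", "C", "G", "T"), n, TRUE)
  # sprinkle CCGG motifs to guarantee cut sites
  k <- max(1L, rpois(1L, p_ccgg * n / 4))
  pos <- sample.int(max(n - 4L, 1L), min(k, max(n - 4L, 1L)))
  for (p in pos) s[p:(p + 3L)] <- c("C", "C", "G", "G")
  paste(s, collapse = "")
}
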