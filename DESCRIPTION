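Package: methvar
Title: Fragment-Level Inter-Individual DNA Methylation Variability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of inter-individual DNA methylation variability in
    reduced-representation bisulfite sequencing (RRBS) data using MspI
    restriction fragments as the unit of analysis.  Provides in silico
    MspI digestion of a genome into the reduced-representation fragment
    universe, aggregation of per-CpG bisulfite calls to fragments per
    individual with coverage-based qualification, a chi-square homogeneity
    test across individuals with Bonferroni family-wise control to call
    inter-individual variably methylated fragments (iVMFs), dispersion
    diagnostics (SD, binomial-scaled CV, logit transforms), gene and
    CpG-island context annotation with per-gene variability scores and
    variably methylated gene calling, Yates-corrected contingency-table
    enrichment statistics and hypergeometric gene-list overlap, and
    integration of fragment methylation with gene- and exon-level
    expression.  A seeded synthetic-data generator with planted ground
    truth supports calibration, power and end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Biostrings,
    BiocGenerics,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
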