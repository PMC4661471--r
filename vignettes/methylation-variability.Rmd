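---
title: "Fragment-level methylation variability: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-level methylation variability: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methvar)
```

## Why fragments

RRBS libraries are built by MspI digestion (cutting at C^CGG) followed by
size selection, so the sequenced genome fraction is naturally partitioned
into restriction fragments of 40–220 bp. `methvar` uses these fragments as
the unit of analysis: regional methylation is the biologically meaningful
signal, and summing the CpG read observations of a fragment integrates
information across its CpGs, damping per-CpG sampling noise. Large fixed
tiling windows would do the opposite for RRBS — most windows contain no
reads, and a variable fragment inside a large window is averaged away.

Coordinates are 0-based half-open (BED convention) everywhere inside the
package; 1-based inputs (call files, GTF) are converted at the readers.
CpGs are indexed by the forward-strand C of the dyad, so strand-split
caller output must be (and is, by `read_cpg_calls()`) collapsed by
position. Only internal fragments — cut at both ends — enter the RR
universe, mirroring the library chemistry; chromosome-end stubs are
discarded.

## The homogeneity test

For one fragment, let individual $i$ contribute $m_i$ methylated and
$u_i$ unmethylated CpG read observations (summed over the fragment's
CpGs). Under the null hypothesis that all individuals share one
methylation proportion, the $k \times 2$ table has expected cells
$E = \text{row total} \times \text{column total} / \text{grand total}$ and

$$\chi^2 = \sum_{\text{cells}} \frac{(O - E)^2}{E}, \qquad df = k - 1 .$$

The test treats each CpG read observation as an independent Bernoulli
draw. That is knowingly optimistic — observations at neighbouring CpGs of
one fragment are correlated — which is why the base significance level is
a stringent $\alpha = 0.001$ rather than 0.05. Family-wise error over the
$m$ analysed fragments is then controlled by Bonferroni; the caller uses
the *current run's* analysed count as the family size, never a hard-coded
constant. The iVMF rule is inclusive, $p \le \alpha/m$: the boundary
convention matters only at measure-zero ties but is fixed and tested.
No continuity correction is applied in the $k \times 2$ test; the Yates
correction is reserved for the 2 x 2 enrichment tables, where it is the
field's convention.

Degenerate inputs are handled by rule, not by error:

* an individual with $m_i + u_i = 0$ is dropped and $k$ reduced;
* fewer than 2 usable individuals gives an untestable sentinel (`NA`);
* a zero pooled column (all observations methylated, or none) means no
  observable variation in proportion: the test returns
  $(\chi^2 = 0,\, p = 1)$.

Qualification and testing are decoupled: a fragment–individual pair
qualifies when at least 2 CpGs each carry 10 or more reads (the per-CpG
reading of the inclusion filter; an alternative fragment-total reading is
available via `mode = "fragment_total"` for sensitivity analysis), but the
test itself uses *all* CpG observations of qualified individuals, because
the fragment methylation proportion is defined over all reads.
Non-qualified individuals are dropped from that fragment's test rather
than imputed. A fragment is analysed when it qualifies in at least 9 of 11
individuals (both numbers configurable).

## Dispersion diagnostics

Because methylation lives on a bounded 0–100% scale, the raw SD of
per-individual percentages is misleading near the boundaries: fragments
pinned at 0% or 100% necessarily have small SD. The package therefore also
reports a binomial-scaled (modified) coefficient of variation,
$\text{CV} = s / \sqrt{\bar x (100 - \bar x)/k}$, and log/logit
transforms ($\log s$, $\log \text{CV}$, $\mathrm{logit}(\bar x) =
\log[\bar x / (100 - \bar x)]$) that spread the extremes;
`plot(fit, which = "log_sd")` shows variable fragments separating cleanly
from the background in those coordinates. Sample (n−1) standard deviation
and natural logarithms are used throughout; the modified CV and logit are
`NA` sentinels at mean 0 or 100, as is the log of a zero dispersion.

## Annotation conventions

Fragments are placed relative to protein-coding gene models. A fragment
overlapping a gene is `tss_overlap` if it covers the TSS, otherwise
classified by its exon-overlap pattern (wholly inside an exon, wholly
intronic, or a junction class oriented by transcription direction). A
fragment outside all genes is assigned to the nearest gene for which it
lies strand-aware upstream of the TSS, with the TSS-to-closest-edge
distance binned 0–2 kb, 2–5 kb (promoter, i.e. up to 5 kb upstream of the
gene start), 5–10 kb, and >10 kb ("distant"). The rare fragment downstream
of every gene on its chromosome falls into the distant class. Equidistant
ties break lexicographically by gene id, with a warning. CpG-island
context uses the fragment midpoint — core inside the island, shore within
2 kb of an edge, shelf within 2–4 kb — so a fragment contributes to
exactly one band and band-edge double counting cannot occur.

Per-gene variability scores divide a gene's iVMF count by its analysed
fragment count. For the gene-level score, no limit is placed on how far
upstream an associated fragment may lie; region-class scores (promoter,
gene body) restrict to the matching context categories. A variably
methylated gene needs at least 3 iVMFs *and* a score of at least 0.5 —
the count gate prevents one- or two-fragment genes from topping the list
with a score of 1.

Enrichment statistics are plain contingency tables: the strong-overlap
rule flags a fragment when at least 50% of its length (inclusive) is
covered by the merged feature track; per-chromosome tests compare "this
chromosome vs the rest" between the iVMF set and the RR genome; the Yates
statistic clamps to zero when the correction exceeds $|ad - bc|$.
Enrichment p-values are reported unadjusted at $\alpha = 0.05$.
Hypergeometric overlap of gene lists defaults its universe to the
protein-coding gene count of the supplied annotation, overridable because
no universally right universe exists.

## Expression integration

Gene abundance is compared across fragment-methylation bins
$[0,30]$, $(30,70]$, $(70,100]$ (the boundary value 30 belongs to the
lower bin) on the $\log(\text{abundance} + 0.1)$ scale, with one-way ANOVA
and Tukey HSD letters. Exon-level analysis correlates methylation with
$\log_2(\text{count} + 1)$; the pseudo-count conventions are documented
and configurable offsets. In the iVMF–exon-inclusion analysis, each
(iVMF, individual) pair contributes equally to the pooled correlations —
pairs are not first aggregated per exon — and the previous/next exons in
transcription order serve as local controls, skipped where a first/last
exon has no neighbour. Equal pair weighting makes the pooled r easy to
define but means pairs sharing an exon are not independent; the effective
sample size is closer to the number of distinct exons, which is why the
package's own reproducibility checks run this analysis over many seeded
replicates rather than trusting a single pooled p-value.

## The synthetic cohort

The generator exists so that every stage of the pipeline can be exercised
against known truth without any external download. It emulates:

* a cohort of 11 individuals over a miniature multi-chromosome genome
  with CCGG sites planted at ~8/kb (unplanted CCGG occurrences are
  actively scrubbed, so the motif density is controlled exactly; density
  0 yields a genome with no MspI site at all);
* bimodal fragment methylation — an unmethylated mode near 3% and a
  methylated mode near 88%, with island/promoter fragments drawn from the
  unmethylated mode with probability 0.8 and the background mostly
  methylated (mixture weight 0.65), reproducing the hypomethylated
  promoter / hypermethylated background structure of a real methylome;
* beta-binomial counts: each individual's true fragment methylation is a
  Beta draw around the fragment mean, with concentration 300 for
  non-variable fragments (per-individual SD ≈ 2–3 percentage points, like
  real non-variable fragments) and 6 for the planted variable minority
  (intermediate means, SD ≈ 15–19 points); per-CpG coverage is negative
  binomial (mean 20, size 4), making the qualification filter bite
  realistically; `dispersion_null = Inf` collapses the Beta to its mean
  and provides the exact binomial null used for type-I calibration;
* an optional pseudo-X chromosome with sex-differential fragments
  (females ~75%, males ~15%) to exercise the two-group ANOVA and the
  ≥20-point mean-difference filter;
* expression tables with two planted effects: gene abundance inversely
  coupled to the methylation of fragments 0–500 bp downstream of the TSS,
  and linked-exon log2 counts correlated with their fragment's
  methylation at a configurable target (default 0.7), with adjacent exons
  left uncoupled so the local-effect contrast is testable.

Randomness is stream-split: fragment-level truth uses the global seed,
each individual a derived sub-seed, so enlarging the cohort never changes
existing individuals' data.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: read-level artefacts (no FASTQ,
alignment or bisulfite-conversion error), correlation between neighbouring
CpGs within a fragment (observations are conditionally independent given
the fragment's per-individual methylation, so the chi-square's main
real-data liability is absent by construction), PCR duplication and
coverage bias beyond NB over-dispersion, SNPs and allele-specific
methylation, and any realistic effect-size distribution for variable
fragments — the planted dispersion is chosen for testability, since no
empirical distribution of real iVMF effect sizes is established.

## Problem sizes and reproducibility checks

The packaged checks run at sizes chosen to finish in minutes on one CPU
while keeping Monte-Carlo error useful: type-I calibration on 10,000 null
fragments (the fraction with $p \le 0.001$ must sit within 3 binomial
standard errors of 0.001, and nothing may pass Bonferroni); recovery of
10% planted variable fragments among 5,000 (sensitivity ≥ 0.9, FDR ≤ 0.1
at the Bonferroni cutoff); 1,000-table agreement of both chi-square
implementations with the stock `chisq.test()` to 1e-9 relative; digestion
against a naive substring scan on 100 random chromosomes; and the local
exon effect over 20 end-to-end runs on 250 kb genomes — large enough that
each run carries ~30 linked exons, so the pooled control correlations are
stable and the overlapped-exon correlation is expected to dominate in
essentially every run.

## Known limitations

* The chi-square inherits the independence assumption discussed above; on
  real data its p-values are anti-conservative, mitigated (not fixed) by
  the stringent base level. No spatial-correlation correction is applied.
* Bonferroni is the only calling procedure; a q-value column would be a
  harmless extra but is deliberately not used for calling.
* Promoter definitions are gene-level, not transcript-isoform aware.
* The differential-exon flag is an input; the package does not implement
  a differential exon-usage model.
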