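#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic-data generator.
#' The defaults describe the study design the generator emulates: a small
#' cohort (11 individuals) of one homogeneous cell type, RRBS coverage of a
#' CpG-dense reduced-representation genome, bimodal fragment methylation
#' (an unmethylated mode near 3% and a methylated mode near 88%), tight
#' inter-individual dispersion for most fragments and a planted minority of
#' highly dispersed (variable) fragments.
#'
#' @param seed Integer seed governing all randomness.  Per-individual
#'   random streams are derived from it so that adding individuals does not
#'   change the data of existing ones.
#' @param n_individuals Cohort size (default 11).
#' @param n_chromosomes Number of autosomes in the synthetic genome.
#' @param chrom_length Chromosome length in bp.
#' @param ccgg_density Target MspI (CCGG) sites per kb.
#' @param frac_variable Proportion of RR fragments planted as variable.
#' @param base_meth_profile Named numeric: mixture weights `low` and `high`
#'   for the unmethylated (~3%) and methylated (~88%) fragment modes; must
#'   sum to 1.
#' @param meth_modes Named numeric: the `low` and `high` mode means on the
#'   proportion scale.
#' @param dispersion_null Beta concentration (a+b) for non-variable
#'   fragments; larger means tighter across individuals.  `Inf` makes the
#'   per-individual methylation exactly the fragment mean (pure binomial
#'   sampling), the calibration null of the chi-square test.
#' @param dispersion_variable Beta concentration for planted variable
#'   fragments; must be smaller than `dispersion_null`.
#' @param coverage_mean Mean reads per CpG (negative-binomial, size
#'   `coverage_size`).
#' @param coverage_size Negative-binomial size (inverse over-dispersion) of
#'   per-CpG coverage.
#' @param expression_coupling Target Pearson correlation between the
#'   methylation of an exon-linked variable fragment and the log2 read
#'   count of the linked exon.
#' @param sexes Optional character vector (`"M"`/`"F"`) of length
#'   `n_individuals`.  When supplied and `n_individuals >= 4`, a pseudo-X
#'   chromosome with sex-differential fragments is generated to exercise
#'   the two-group ANOVA path.
#' @param frac_sex_diff Proportion of chrX RR fragments made
#'   sex-differential (females methylated, males unmethylated).
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_individuals = 11L,
                       n_chromosomes = 2L,
                       chrom_length = 150000L,
                       ccgg_density = 8,
                       frac_variable = 0.1,
                       base_meth_profile = c(low = 0.35, high = 0.65),
                       meth_modes = c(low = 0.03, high = 0.88),
                       dispersion_null = 300,
                       dispersion_variable = 6,
                       coverage_mean = 20,
                       coverage_size = 4,
                       expression_coupling = 0.7,
                       sexes = NULL,
                       frac_sex_diff = 0.5) {
  cfg <- list(seed = as.integer(seed), n_individuals = as.integer(n_individuals),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.integer(chrom_length),
              ccgg_density = ccgg_density, frac_variable = frac_variable,
              base_meth_profile = base_meth_profile, meth_modes = meth_modes,
              dispersion_null = dispersion_null,
              dispersion_variable = dispersion_variable,
              coverage_mean = coverage_mean, coverage_size = coverage_size,
              expression_coupling = expression_coupling,
              sexes = sexes, frac_sex_diff = frac_sex_diff)
  if (cfg$chrom_length <= 0L) stop("chrom_length must be positive")
  if (cfg$n_chromosomes < 1L) stop("need at least one chromosome")
  if (cfg$n_individuals < 1L) stop("need at least one individual")
  if (cfg$frac_variable < 0 || cfg$frac_variable > 1)
    stop("frac_variable must lie in [0, 1]")
  if (abs(sum(cfg$base_meth_profile) - 1) > 1e-8)
    stop("base_meth_profile weights must sum to 1")
  if (any(cfg$meth_modes < 0 | cfg$meth_modes > 1))
    stop("meth_modes must lie in [0, 1]")
  if (cfg$coverage_mean < 1) stop("coverage_mean must be >= 1")
  if (cfg$dispersion_variable >= cfg$dispersion_null)
    stop("dispersion_variable must be smaller than dispersion_null")
  if (abs(cfg$expression_coupling) > 1)
    stop("expression_coupling must lie in [-1, 1]")
  if (!is.null(cfg$sexes)) {
    if (length(cfg$sexes) != cfg$n_individuals)
      stop("sexes must have length n_individuals")
    if (!all(cfg$sexes %in% c("M", "F")))
      stop("sexes must be 'M' or 'F'")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic RRBS cohort configuration\n")
  cat(sprintf("  individuals: %d%s\n", x$n_individuals,
              if (is.null(x$sexes)) "" else
                sprintf(" (%d M / %d F, pseudo-X enabled)",
                        sum(x$sexes == "M"), sum(x$sexes == "F"))))
  cat(sprintf("  genome: %d chromosome(s) x %d bp, ~%.1f CCGG/kb\n",
              x$n_chromosomes, x$chrom_length, x$ccgg_density))
  cat(sprintf("  methylation modes: low %.0f%% (w=%.2f), high %.0f%% (w=%.2f)\n",
              100 * x$meth_modes[["low"]], x$base_meth_profile[["low"]],
              100 * x$meth_modes[["high"]], x$base_meth_profile[["high"]]))
  cat(sprintf("  dispersion (beta concentration): null %s, variable %s; planted fraction %.2f\n",
              format(x$dispersion_null), format(x$dispersion_variable),
              x$frac_variable))
  cat(sprintf("  coverage: NB(mean %.0f, size %.0f) reads per CpG\n",
              x$coverage_mean, x$coverage_size))
  invisible(x)
}

# Deterministic per-individual seed stream: individual j always gets the
# same sub-seed regardless of how many individuals are simulated.
individual_seed <- function(seed, j) {
  (as.integer(seed) * 1009L + 7919L * as.integer(j)) %% 2147483629L
}
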