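#' Standard evaluation scenarios
#'
#' Canned [sim_config()] objects for the three simulation studies the
#' package uses to characterize its operating behaviour.  Their parameters
#' are the study conditions, chosen once:
#'
#' * `selection_scenario_config()`: four groups of 100 accessions with a
#'   flat baseline A frequency of 0.6 (null loci have no frequency change
#'   between stages) and 20 sweep loci forced along the trajectory
#'   0.6 (wild) -> 0.32 (early domesticate) -> 0.05 (heirloom and modern),
#'   i.e. a completed domestication sweep toward the cultivar allele.
#' * `introgression_scenario_config()`: one 10-Mb chromosome carrying ~400
#'   SVs; the cultivated groups are near-fixed for the cultivar allele
#'   (A frequency 0.01) so that wild-like haplotype segments arise from the
#'   planted introgression and not from standing variation, and one
#'   wild-donor introgression is planted into 10% of modern accessions
#'   over 3.0-5.0 Mb.
#' * `eqtl_scenario_config()`: 150 accessions (30/40/40/40 across stages),
#'   2,000 SVs over two 10-Mb chromosomes (one SV per ~10 kb, so cis
#'   windows hold several linked SVs), 300 genes, 20 planted cis effects of
#'   2.0 expression units per A-allele dose (the simulator's reference
#'   effect size), and one trans hotspot: a regulator gene with its own cis
#'   SV (effect 2.0) driving 15 target genes with weight 1.0.  Causal SVs
#'   are fixed evenly spaced indices;
#'   every locus has a pooled minor allele frequency near 0.19 under the
#'   default trajectory, comfortably above the 1% association filter.
#'
#' @param seed RNG seed.
#' @return a [sim_config()] object.
#' @export
selection_scenario_config <- function(seed = 1L) {
  n_loci <- 200L
  sweeps <- data.frame(sv = seq(5L, n_loci, by = 10L))
  sweeps$SP <- 0.6; sweeps$SLC <- 0.32
  sweeps$heirloom <- 0.05; sweeps$modern <- 0.05
  sim_config(
    seed = seed, n_chromosomes = 2L, chrom_length = 5e6,
    n_deletions = 120L, n_insertions = 70L, n_inversions = 10L,
    snp_rate = 0,
    group_sizes = c(SP = 100L, SLC = 100L, heirloom = 100L, modern = 100L),
    group_freq_a = c(SP = 0.6, SLC = 0.6, heirloom = 0.6, modern = 0.6),
    selected_loci = sweeps)
}

#' @rdname selection_scenario_config
#' @export
introgression_scenario_config <- function(seed = 1L) {
  sim_config(
    seed = seed, n_chromosomes = 1L, chrom_length = 10e6,
    n_deletions = 250L, n_insertions = 130L, n_inversions = 20L,
    snp_rate = 0,
    group_sizes = c(SP = 50L, SLC = 50L, heirloom = 50L, modern = 50L),
    group_freq_a = c(SP = 0.60, SLC = 0.16, heirloom = 0.001,
                     modern = 0.001),
    introgression_blocks = data.frame(
      group = "modern", frac = 0.10, chrom = "chr1",
      start = 3e6, end = 5e6, stringsAsFactors = FALSE))
}

#' @rdname selection_scenario_config
#' @param n_cis number of planted cis effects.
#' @param cis_beta cis effect size (expression units per A-allele dose).
#' @export
eqtl_scenario_config <- function(seed = 1L, n_cis = 20L, cis_beta = 2.0) {
  n_sv <- 2000L
  causal <- round(seq(60L, n_sv - 300L, length.out = n_cis))
  sim_config(
    seed = seed, n_chromosomes = 2L, chrom_length = 10e6,
    n_deletions = 1200L, n_insertions = 700L, n_inversions = 100L,
    sv_size_range = c(20, 200), snp_rate = 0,
    group_sizes = c(SP = 30L, SLC = 40L, heirloom = 40L, modern = 40L),
    recomb_mean_segment = 5e5,
    n_genes = 300L,
    cis_effects = data.frame(gene = seq_len(n_cis), sv = causal,
                             beta = cis_beta),
    hotspot = list(regulator_gene = 150L, regulator_sv = n_sv - 150L,
                   regulator_beta = 2.0,
                   targets = 200L:214L, beta = 1.0),
    noise_sd = 1)
}
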