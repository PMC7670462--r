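#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by all simulator
#' functions ([simulate_genome_pair()], [simulate_population_genotypes()],
#' [simulate_read_evidence()], [simulate_expression()]).  Defaults describe a
#' small two-chromosome toy system with a four-stage population
#' (wild progenitor SP, early domesticate SLC, heirloom, modern) whose group
#' allele frequencies follow the domestication trajectory observed in tomato:
#' wild-reference ("A") alleles common in SP and progressively replaced by
#' cultivar-reference ("B") alleles through domestication and improvement,
#' with a slight recovery in modern lines.
#'
#' All internal coordinates are 0-based half-open; emitted SAM/VCF/GFF3 use
#' their standard 1-based conventions.
#'
#' @param seed integer seed; the same configuration yields byte-identical
#'   outputs from every simulator function.
#' @param n_chromosomes number of chromosomes in the toy genomes.
#' @param chrom_length chromosome length in bp.
#' @param n_deletions,n_insertions,n_inversions planted SV counts
#'   (deletion = segment present in genome A, absent in B; insertion the
#'   reverse; inversion length-preserving).
#' @param sv_size_range two-element bp interval for SV sizes; minimum 10 bp.
#' @param snp_rate per-bp probability of a planted SNP outside SV regions.
#' @param group_sizes named counts of accessions for the four population
#'   groups, in order SP, SLC, heirloom, modern.
#' @param group_freq_a named per-group mean frequency of the A (wild) allele.
#' @param drift_sd per-locus frequency-scale noise (SD of the per-locus
#'   flip-probability deviation in the mosaic haplotype model).
#' @param inbreeding probability that an accession's two haplotypes are
#'   identical copies (selfing rate); tomato is highly autogamous.
#' @param recomb_mean_segment mean archetype-mosaic segment length in bp;
#'   controls the physical scale of linkage disequilibrium.
#' @param founder_flip baseline per-locus probability that a haplotype's
#'   allele departs from its mosaic archetype (keeps neighbouring loci from
#'   being perfect copies of one another).
#' @param missing_rate probability that a genotype call is set to missing.
#' @param selected_loci data.frame with columns `sv` (SV index) and one
#'   column per group giving the forced A-allele target frequency, or NULL.
#' @param introgression_blocks data.frame with columns `group`
#'   ("heirloom"/"modern"), `frac` (fraction of accessions carrying the
#'   introgression), `chrom`, `start`, `end` (bp, 0-based half-open), or NULL.
#' @param read_depth fold coverage for read-evidence simulation.
#' @param read_length read length in bp.
#' @param n_genes number of expressed genes for the expression simulator.
#' @param cis_effects data.frame with columns `gene` (gene index), `sv`
#'   (SV index) and `beta` (expression change per A-allele dose), or NULL.
#' @param hotspot list with elements `regulator_gene`, `regulator_sv`,
#'   `regulator_beta`, `targets` (gene indices) and `beta` (effect of the
#'   regulator's expression on each target), or NULL.
#' @param expr_baseline baseline expression level.
#' @param noise_sd expression noise SD.
#'
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 5e5,
                       n_deletions = 12L,
                       n_insertions = 8L,
                       n_inversions = 2L,
                       sv_size_range = c(20, 500),
                       snp_rate = 2e-4,
                       group_sizes = c(SP = 50L, SLC = 100L,
                                       heirloom = 100L, modern = 50L),
                       group_freq_a = c(SP = 0.60, SLC = 0.16,
                                        heirloom = 0.05, modern = 0.065),
                       drift_sd = 0.005,
                       inbreeding = 0.95,
                       recomb_mean_segment = 2e6,
                       founder_flip = 0.005,
                       missing_rate = 0.02,
                       selected_loci = NULL,
                       introgression_blocks = NULL,
                       read_depth = 20,
                       read_length = 100L,
                       n_genes = 50L,
                       cis_effects = NULL,
                       hotspot = NULL,
                       expr_baseline = 5,
                       noise_sd = 1) {
  cfg <- list(seed = as.integer(seed),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.numeric(chrom_length),
              n_deletions = as.integer(n_deletions),
              n_insertions = as.integer(n_insertions),
              n_inversions = as.integer(n_inversions),
              sv_size_range = as.numeric(sv_size_range),
              snp_rate = snp_rate,
              group_sizes = group_sizes,
              group_freq_a = group_freq_a,
              drift_sd = drift_sd,
              inbreeding = inbreeding,
              recomb_mean_segment = recomb_mean_segment,
              founder_flip = founder_flip,
              missing_rate = missing_rate,
              selected_loci = selected_loci,
              introgression_blocks = introgression_blocks,
              read_depth = read_depth,
              read_length = as.integer(read_length),
              n_genes = as.integer(n_genes),
              cis_effects = cis_effects,
              hotspot = hotspot,
              expr_baseline = expr_baseline,
              noise_sd = noise_sd)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_chromosomes, cfg$n_deletions, cfg$n_insertions,
              cfg$n_inversions, cfg$n_genes, cfg$group_sizes)
  if (any(counts < 0)) stop("all counts must be >= 0")
  if (length(cfg$sv_size_range) != 2 || cfg$sv_size_range[1] < 10)
    stop("sv_size_range must be an interval with minimum >= 10 bp")
  if (cfg$sv_size_range[2] < cfg$sv_size_range[1])
    stop("sv_size_range must be non-decreasing")
  if (any(cfg$group_freq_a < 0 | cfg$group_freq_a > 1))
    stop("group frequencies must lie in [0, 1]")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (cfg$inbreeding < 0 || cfg$inbreeding > 1)
    stop("inbreeding must lie in [0, 1]")
  if (!is.null(cfg$selected_loci)) {
    sl <- cfg$selected_loci
    if (!all(c("sv", names(cfg$group_sizes)) %in% names(sl)))
      stop("selected_loci needs columns: sv plus one per group")
    tf <- as.matrix(sl[, names(cfg$group_sizes), drop = FALSE])
    if (any(tf < 0 | tf > 1, na.rm = TRUE))
      stop("target frequencies must lie in [0, 1]")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration (seed ", x$seed, ")\n", sep = "")
  cat("  genomes: ", x$n_chromosomes, " chromosome(s) of ",
      format(x$chrom_length, big.mark = ","), " bp\n", sep = "")
  cat("  planted SVs: ", x$n_deletions, " deletions, ", x$n_insertions,
      " insertions, ", x$n_inversions, " inversions\n", sep = "")
  cat("  population: ", paste(names(x$group_sizes), x$group_sizes,
                              sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Stage-specific RNG streams derived from the one configured seed, so that
# e.g. regenerating expression does not perturb the genotype draw.  Offsets
# are fixed constants; all stay far below .Machine$integer.max.
stage_seed <- function(cfg, stage) {
  offsets <- c(genome = 0L, population = 1000L, reads = 2000L,
               expression = 3000L, callsets = 4000L)
  cfg$seed %% 100000L + offsets[[stage]] * 10000L
}
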