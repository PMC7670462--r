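#' Simulation-study evaluation harnesses
#'
#' Each function runs one of the standard scenarios end to end against the
#' known truth and reports recovery metrics.  They are the package's own
#' operating-characteristic studies: genotype calling from read evidence,
#' the selection scan's power and false-positive rate, window-level
#' introgression recovery, and cis-eQTL / hotspot recovery.
#'
#' @param seed RNG seed for the scenario.
#' @param n_cases number of (SV, accession, genotype) cases to draw.
#' @param depth fold coverage for read simulation.
#' @return `evaluate_genotyping_recovery()`: list with `accuracy`,
#'   `n_cases`, and `missing_at_zero_depth` (fraction of calls that are
#'   missing when depth is 0).
#' @export
evaluate_genotyping_recovery <- function(seed = 1, n_cases = 200,
                                         depth = 15) {
  cfg <- sim_config(seed = seed, n_chromosomes = 2L, chrom_length = 2e5,
                    n_deletions = 8L, n_insertions = 6L, n_inversions = 4L,
                    sv_size_range = c(40, 300), read_depth = depth)
  pair <- simulate_genome_pair(cfg)
  svs <- pair$truth$svs
  set.seed(seed * 1000L + 1L)
  cases <- data.frame(sv = sample(nrow(svs), n_cases, replace = TRUE),
                      g = sample(c("A_HOM", "B_HOM", "HET"), n_cases,
                                 replace = TRUE, prob = c(0.4, 0.4, 0.2)))
  calls <- vapply(seq_len(n_cases), function(i) {
    aln <- simulate_read_evidence(pair, svs[cases$sv[i], ], cases$g[i],
                                  cfg, accession = paste0("case", i))
    call_genotype(collect_evidence(aln$aln_a, aln$aln_b,
                                   svs[cases$sv[i], ]))
  }, character(1))
  cfg0 <- cfg; cfg0$read_depth <- 0
  zero <- vapply(seq_len(20), function(i) {
    aln <- suppressWarnings(simulate_read_evidence(
      pair, svs[(i %% nrow(svs)) + 1L, ], "A_HOM", cfg0,
      accession = paste0("z", i)))
    call_genotype(collect_evidence(aln$aln_a, aln$aln_b,
                                   svs[(i %% nrow(svs)) + 1L, ]))
  }, character(1))
  list(accuracy = mean(calls == cases$g), n_cases = n_cases,
       missing_at_zero_depth = mean(zero == "MISSING"))
}

#' @rdname evaluate_genotyping_recovery
#' @param pair_groups the two groups compared in the Fisher scan.
#' @return `evaluate_selection_recovery()`: list with `power` (fraction of
#'   planted sweeps flagged), `fpr` (fraction of null loci flagged) and
#'   `n_sweeps`, `n_null`.
#' @export
evaluate_selection_recovery <- function(seed = 1,
                                        pair_groups = c("SP", "heirloom")) {
  cfg <- selection_scenario_config(seed)
  pair <- simulate_genome_pair(cfg)
  gm <- simulate_population_genotypes(pair$truth, cfg)
  freqs <- group_allele_frequencies(gm)
  res <- fisher_selection_scan(freqs, pair_groups)
  sweep_ids <- gm$sites$sv_id[cfg$selected_loci$sv]
  is_sweep <- res$sv_id %in% sweep_ids
  list(power = mean(res$selected[is_sweep]),
       fpr = mean(res$selected[!is_sweep]),
       n_sweeps = sum(is_sweep), n_null = sum(!is_sweep))
}

#' @rdname evaluate_genotyping_recovery
#' @return `evaluate_introgression_recovery()`: list with window-level
#'   `recall` (over windows fully inside the planted block, for planted
#'   accessions) and `precision` (detections overlapping the block).
#' @export
evaluate_introgression_recovery <- function(seed = 1) {
  cfg <- introgression_scenario_config(seed)
  pair <- simulate_genome_pair(cfg)
  gm <- simulate_population_genotypes(pair$truth, cfg)
  lens <- vapply(pair$genome_a, nchar, numeric(1))
  seg <- introgression_scan(gm, chrom_lengths = lens)
  blk <- cfg$introgression_blocks
  win_starts <- seq(0, lens[[blk$chrom]] - 1, by = 250e3)
  full <- win_starts[win_starts >= blk$start &
                       win_starts + 1e6 <= blk$end]
  overl <- win_starts[win_starts < blk$end & win_starts + 1e6 > blk$start]
  acc <- unique(gm$introgressions$accession)
  det <- paste(seg$accession, seg$start)
  list(recall = mean(as.vector(outer(acc, full, paste)) %in% det),
       precision = if (length(det))
         mean(det %in% as.vector(outer(acc, overl, paste))) else NA,
       n_detected = nrow(seg))
}

#' @rdname evaluate_genotyping_recovery
#' @param pipeline a [pipeline_config()].
#' @return `evaluate_eqtl_recovery()`: list with `cis_recovery` (fraction
#'   of planted cis effects yielding a cis block containing the causal SV),
#'   `hotspot_detected`, `regulator_top` (the planted regulator ranked
#'   first in the best hotspot), and block counts.
#' @export
evaluate_eqtl_recovery <- function(seed = 1,
                                   pipeline = pipeline_config()) {
  cfg <- eqtl_scenario_config(seed)
  pair <- simulate_genome_pair(cfg)
  gm <- simulate_population_genotypes(pair$truth, cfg)
  es <- simulate_expression(gm, cfg)
  eq <- map_eqtls(gm, es, pipeline,
                  vapply(pair$genome_a, nchar, numeric(1)))
  blocks <- eq$blocks
  cis <- cfg$cis_effects
  rec <- vapply(seq_len(nrow(cis)), function(i) {
    b <- blocks[blocks$gene_id == sprintf("gene%04d", cis$gene[i]) &
                  blocks$class == "cis", , drop = FALSE]
    if (!nrow(b)) return(FALSE)
    any(vapply(strsplit(b$members, ","), function(mm)
      gm$sites$sv_id[cis$sv[i]] %in% mm, logical(1)))
  }, logical(1))
  hs <- eq$hotspots
  reg_gene <- sprintf("gene%04d", cfg$hotspot$regulator_gene)
  best <- if (nrow(hs)) hs[which.max(hs$n_targets), ] else NULL
  list(cis_recovery = mean(rec),
       hotspot_detected = !is.null(best),
       regulator_top = !is.null(best) &&
         identical(best$candidate_regulator, reg_gene),
       n_blocks = nrow(blocks),
       n_cis_blocks = sum(blocks$class == "cis"),
       n_trans_blocks = sum(blocks$class == "trans"))
}
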