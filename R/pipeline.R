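#' Pipeline configuration with the study's default thresholds
#'
#' Collects every tunable of the analysis stages with its default value:
#' 50-bp gap distance, 0.9 inversion split-read fraction, the 20% / 3-bp
#' flank-geometry rules, 3 split reads per breakpoint, 40% genotyping
#' completeness, corrected-P < 0.001 selection cutoff, 1000-kb windows with
#' 250-kb steps, 0.9 sharing ratio with at least 2 SVs for introgressions,
#' MAF >= 1% and missing <= 40% for association sites, Bonferroni alpha
#' levels 0.05 and 1, and 50-kb cis and hotspot windows.  Every entry can
#' be overridden by name.
#'
#' @param ... overrides, e.g. `gap_min_dist = 100`.
#' @param seed seed forwarded to simulation stages.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(..., seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    gap_min_dist = 50,
    inversion_split_frac = 0.9,
    insertion_size_tol = 0.2,
    deletion_gap_tol = 3,
    min_split_reads = 3,
    min_genotyped = 0.40,
    merge_reciprocal = 0.5,
    selection_p = 0.001,
    window = 1e6,
    window_step = 250e3,
    introgression_ratio = 0.9,
    introgression_min_svs = 2,
    maf = 0.01,
    max_missing = 0.40,
    alpha_significant = 0.05,
    alpha_suggestive = 1,
    n_hidden_factors = 20,
    cis_window = 50e3,
    hotspot_window = 50e3,
    hotspot_adj_p = 0.05)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown pipeline setting(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Run the simulated end-to-end analysis
#'
#' Drives the full pipeline on synthetic data: simulate a genome pair and
#' caller-style SV records, validate and merge them into a reference SV
#' set, simulate population genotypes, run the selection scan for the three
#' stage transitions, genotype composition, windowed diversity/F_ST and the
#' introgression scan, then the eQTL stage (expression simulation,
#' normalization, imputation, kinship, hidden factors, mixed-model scan,
#' LD background, block construction, hotspot detection and
#' master-regulator ranking).
#'
#' @param sim a [sim_config()] object describing the scenario.
#' @param pipeline a [pipeline_config()].
#' @param stages subset of `c("validate", "popgen", "eqtl")`.
#' @param n_factors_cap hidden factors are capped at accessions/4 for tiny
#'   scenarios.
#' @return named list with per-stage results and the simulation truth.
#' @export
run_pipeline <- function(sim = sim_config(),
                         pipeline = pipeline_config(seed = sim$seed),
                         stages = c("validate", "popgen", "eqtl"),
                         n_factors_cap = TRUE) {
  out <- list(sim_config = sim, pipeline_config = pipeline)
  pair <- simulate_genome_pair(sim)
  out$truth <- pair$truth
  chrom_lengths <- vapply(pair$genome_a, nchar, numeric(1))
  out$chrom_lengths <- chrom_lengths

  if ("validate" %in% stages) {
    cs <- simulate_sv_callsets(pair$truth, sim)
    out$reference_svs <- build_reference_sv_set(
      cs$assemblytics, cs$read_calls, cs$flank_hits, cs$inversion_evidence,
      cs$gaps_a, cs$gaps_b, pipeline$gap_min_dist,
      pipeline$merge_reciprocal)
  }

  gm <- simulate_population_genotypes(pair$truth, sim)
  out$genotypes <- gm

  if ("popgen" %in% stages) {
    freqs <- group_allele_frequencies(gm)
    out$frequencies <- freqs
    prs <- list(c("SP", "SLC"), c("SLC", "heirloom"),
                c("heirloom", "modern"))
    prs <- Filter(function(p) all(p %in% gm$groups), prs)
    out$selection <- do.call(rbind, lapply(prs, function(p)
      fisher_selection_scan(freqs, p, pipeline$selection_p)))
    out$composition <- genotype_composition(gm)
    out$windows <- windowed_diversity_fst(gm, pipeline$window,
                                          pipeline$window_step,
                                          chrom_lengths)
    out$introgressions <- introgression_scan(
      gm, window = pipeline$window, step = pipeline$window_step,
      ratio_max = pipeline$introgression_ratio,
      min_svs = pipeline$introgression_min_svs,
      chrom_lengths = chrom_lengths)
  }

  if ("eqtl" %in% stages) {
    es <- simulate_expression(gm, sim)
    out$expression <- es
    eq <- map_eqtls(gm, es, pipeline, chrom_lengths,
                    n_factors_cap = n_factors_cap)
    out[names(eq)] <- eq
  }
  out
}

#' Run the eQTL stage on a genotype matrix and expression set
#'
#' Normalizes expression, imputes genotypes, builds the kinship and hidden
#' factors (module-like components excluded, see
#' [derive_hidden_factors()]), runs the mixed-model scan, estimates
#' background LD, constructs cis/trans eQTL blocks, detects trans hotspots
#' and ranks their master regulators.
#'
#' @param gm a [genotype_matrix()].
#' @param es an expression set (`values` matrix and `genes` table), e.g.
#'   from [simulate_expression()].
#' @param pipeline a [pipeline_config()].
#' @param chrom_lengths named chromosome lengths in bp.
#' @param n_factors_cap cap hidden factors at accessions/4 for tiny inputs.
#' @return list with `bonferroni`, `ld`, `associations` (significant rows),
#'   `blocks`, `hotspots`.
#' @export
map_eqtls <- function(gm, es, pipeline = pipeline_config(),
                      chrom_lengths, n_factors_cap = TRUE) {
  out <- list()
  norm <- normalize_expression(fpkm = es$values)
  acc <- colnames(norm$normalized)
  dos <- knn_impute(gm$dosage[, acc, drop = FALSE])$dosages
  kin <- compute_kinship(dos)
  k <- pipeline$n_hidden_factors
  if (n_factors_cap) k <- min(k, max(0, floor(length(acc) / 4)))
  fac <- derive_hidden_factors(norm$normalized, k,
                               drop_concentrated = TRUE)
  res <- eqtl_scan(norm$normalized, dos, fac, kin,
                   pipeline$maf, pipeline$max_missing, p_keep = 0.01)
  m_tests <- sum(filter_sv_sites(gm$dosage[, acc, drop = FALSE],
                                 pipeline$maf, pipeline$max_missing))
  thr <- bonferroni_threshold(pipeline$alpha_significant, m_tests)
  out$bonferroni <- list(
    significant = thr,
    suggestive = bonferroni_threshold(pipeline$alpha_suggestive, m_tests),
    m = m_tests)
  ld <- ld_background(dos, gm$sites)
  out$ld <- ld
  blocks <- build_eqtl_blocks(res, dos, gm$sites, es$genes,
                              ld$r2_bg, ld$dist_bg, thr$threshold,
                              cis_window = pipeline$cis_window)
  out$associations <- res[res$p < thr$threshold, , drop = FALSE]
  out$blocks <- blocks
  hs <- detect_hotspots(blocks, as.list(chrom_lengths),
                        pipeline$hotspot_window,
                        adj_p_max = pipeline$hotspot_adj_p)
  if (nrow(hs)) {
    hs$candidate_regulator <- vapply(seq_len(nrow(hs)), function(i) {
      r <- tryCatch(rank_master_regulator(hs[i, ], es$values, es$genes),
                    error = function(e) NULL)
      if (is.null(r) || !nrow(r)) NA_character_ else r$candidate[1]
    }, character(1))
  }
  out$hotspots <- hs
  out
}
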