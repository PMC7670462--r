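test_that("a locus forced to frequency 1 in all groups is fixed homozygous", {
  cfg <- tiny_sim(seed = 2, missing_rate = 0,
                  selected_loci = data.frame(sv = 1, SP = 1, SLC = 1,
                                             heirloom = 1, modern = 1))
  pair <- simulate_genome_pair(cfg)
  gm <- simulate_population_genotypes(pair$truth, cfg)
  expect_true(all(gm$dosage[1, ] == 2L))
})

test_that("forced sweep targets are hit within binomial sampling error", {
  cfg <- sim_config(seed = 5, n_chromosomes = 1, chrom_length = 4e5,
                    n_deletions = 8, n_insertions = 0, n_inversions = 0,
                    snp_rate = 0, missing_rate = 0,
                    group_sizes = c(SP = 100L, SLC = 100L,
                                    heirloom = 100L, modern = 100L),
                    selected_loci = data.frame(sv = 2, SP = 0.6, SLC = 0.3,
                                               heirloom = 0.05,
                                               modern = 0.05))
  pair <- simulate_genome_pair(cfg)
  gm <- simulate_population_genotypes(pair$truth, cfg)
  f_modern <- realized_freq_a(gm$dosage, which(gm$groups == "modern"))[2]
  expect_lt(abs(f_modern - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
  f_sp <- realized_freq_a(gm$dosage, which(gm$groups == "SP"))[2]
  expect_lt(abs(f_sp - 0.6), 0.2)
})

test_that("the same seed reproduces the genotype matrix exactly", {
  cfg <- tiny_sim(seed = 9)
  pair <- simulate_genome_pair(cfg)
  g1 <- simulate_population_genotypes(pair$truth, cfg)
  g2 <- simulate_population_genotypes(pair$truth, cfg)
  expect_identical(g1$dosage, g2$dosage)
})

test_that("realized frequencies equal the allele-count definition", {
  cfg <- tiny_sim(seed = 12)
  pair <- simulate_genome_pair(cfg)
  gm <- simulate_population_genotypes(pair$truth, cfg)
  d <- gm$dosage
  manual <- sapply(seq_len(nrow(d)), function(i) {
    x <- d[i, !is.na(d[i, ])]
    (2 * sum(x == 2) + sum(x == 1)) / (2 * length(x))
  })
  expect_equal(unname(realized_freq_a(d)), manual)
})

test_that("empty truth and empty-group trajectories are rejected", {
  cfg <- tiny_sim(seed = 1)
  expect_error(simulate_population_genotypes(
    structure(list(svs = cfg$selected_loci), class = "sv_truth"), cfg))
  cfg2 <- tiny_sim(seed = 1)
  cfg2$group_sizes["modern"] <- 0L
  cfg2$selected_loci <- data.frame(sv = 1, SP = NA, SLC = NA,
                                   heirloom = NA, modern = 0.5)
  pair <- simulate_genome_pair(cfg2)
  expect_error(simulate_population_genotypes(pair$truth, cfg2), "modern")
})

test_that("missing calls are injected near the configured rate", {
  cfg <- tiny_sim(seed = 3, missing_rate = 0.1)
  pair <- simulate_genome_pair(cfg)
  gm <- simulate_population_genotypes(pair$truth, cfg)
  expect_lt(abs(mean(is.na(gm$dosage)) - 0.1), 0.04)
  expect_false(anyNA(gm$truth_dosage))
})

test_that("planted introgressions copy wild genotypes into focal accessions", {
  cfg <- introgression_scenario_config(seed = 4)
  pair <- simulate_genome_pair(cfg)
  gm <- simulate_population_genotypes(pair$truth, cfg)
  tru <- gm$introgressions
  expect_gt(nrow(tru), 0)
  loci <- which(gm$sites$pos >= 3e6 & gm$sites$pos < 5e6)
  for (a in unique(tru$accession)) {
    frac_a <- mean(gm$truth_dosage[loci, a] == 2)
    expect_gt(frac_a, 0.3)  # wild-rich donor haplotype
  }
  # non-introgressed moderns stay cultivar-like there
  others <- setdiff(names(gm$groups)[gm$groups == "modern"], tru$accession)
  expect_lt(mean(gm$truth_dosage[loci, others] == 2), 0.05)
})
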