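test_that("a planted cis effect shifts genotype-class means by beta per dose", {
  cfg <- tiny_sim(seed = 5, missing_rate = 0, noise_sd = 0.5,
                  n_genes = 10,
                  cis_effects = data.frame(gene = 1, sv = 2, beta = 2.0))
  pair <- simulate_genome_pair(cfg)
  gm <- simulate_population_genotypes(pair$truth, cfg)
  es <- simulate_expression(gm, cfg)
  y <- es$values[1, ]
  d <- gm$truth_dosage[2, ]
  fit <- coef(lm(y ~ d))[2]
  expect_lt(abs(fit - 2.0), 0.3)
  # gene placed within the cis window of its SV
  g <- es$genes[1, ]
  expect_equal(g$chrom, gm$sites$chrom[2])
  expect_lte(abs(g$tss - gm$sites$pos[2]), 5e4)
})

test_that("null genes stay uncorrelated with genotypes", {
  cors <- sapply(1:4, function(s) {
    cfg <- sim_config(seed = s, n_chromosomes = 1, chrom_length = 4e5,
                      n_deletions = 10, n_insertions = 0, n_inversions = 0,
                      snp_rate = 0, missing_rate = 0, n_genes = 5,
                      group_sizes = c(SP = 25L, SLC = 25L, heirloom = 25L,
                                      modern = 25L),
                      group_freq_a = c(SP = 0.5, SLC = 0.5, heirloom = 0.5,
                                       modern = 0.5))
    pair <- simulate_genome_pair(cfg)
    gm <- simulate_population_genotypes(pair$truth, cfg)
    es <- simulate_expression(gm, cfg)
    max(abs(cor(es$values[1, ], t(gm$truth_dosage))))
  })
  expect_true(all(cors < 0.3))
})

test_that("zero noise with no effects yields a constant matrix", {
  cfg <- tiny_sim(seed = 5, noise_sd = 0, n_genes = 4)
  pair <- simulate_genome_pair(cfg)
  gm <- simulate_population_genotypes(pair$truth, cfg)
  es <- simulate_expression(gm, cfg)
  expect_true(all(es$values == cfg$expr_baseline))
})

test_that("effects referencing unknown genes or SVs are rejected", {
  cfg <- tiny_sim(seed = 5, n_genes = 4,
                  cis_effects = data.frame(gene = 99, sv = 1, beta = 1))
  pair <- simulate_genome_pair(cfg)
  gm <- simulate_population_genotypes(pair$truth, cfg)
  expect_error(simulate_expression(gm, cfg), "unknown gene")
  cfg$cis_effects <- data.frame(gene = 1, sv = 9999, beta = 1)
  expect_error(simulate_expression(gm, cfg), "unknown SV")
})

test_that("fewer than 20 accessions violates the precondition", {
  cfg <- tiny_sim(seed = 5)
  cfg$group_sizes <- c(SP = 4L, SLC = 4L, heirloom = 4L, modern = 4L)
  pair <- simulate_genome_pair(cfg)
  gm <- simulate_population_genotypes(pair$truth, cfg)
  expect_error(simulate_expression(gm, cfg), "20 accessions")
})

test_that("hotspot targets are trans to the regulator locus and respond to it", {
  cfg <- tiny_sim(seed = 6, missing_rate = 0, n_genes = 20,
                  hotspot = list(regulator_gene = 1L, regulator_sv = 3L,
                                 regulator_beta = 2, targets = 5:8,
                                 beta = 1))
  pair <- simulate_genome_pair(cfg)
  gm <- simulate_population_genotypes(pair$truth, cfg)
  es <- simulate_expression(gm, cfg)
  reg <- es$values[1, ]
  for (t in 5:8) {
    expect_gt(cor(reg, es$values[t, ]), 0.3)
    g <- es$genes[t, ]
    same <- g$chrom == gm$sites$chrom[3] &&
      abs(g$tss - gm$sites$pos[3]) < 1e5
    expect_false(same)
  }
})
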