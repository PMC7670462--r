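test_that("pairwise r2 basics: perfect copies, duplicates at distance zero", {
  set.seed(1)
  g <- rbinom(100, 2, 0.5)
  expect_equal(pair_r2(g, g), 1)
  expect_equal(pair_r2(g, 2 - g), 1)
  expect_equal(pair_r2(g, rep(1, 100)), 0)
  d <- rbind(g, g, rbinom(100, 2, 0.5))
  sites <- data.frame(chrom = "chr1", pos = c(1000, 1000, 9e5))
  ld <- suppressWarnings(ld_background(d, sites, bin_width = 1e4))
  expect_equal(ld$decay$r2[1], 1)   # duplicated site pair in the first bin
})

test_that("independent sites have mean r2 near 1/n", {
  set.seed(2)
  n <- 200
  d <- matrix(rbinom(120 * n, 2, 0.5), 120, n)
  sites <- data.frame(chrom = "chr1",
                      pos = sort(runif(120, 0, 1e7)))
  ld <- ld_background(d, sites, max_dist = 1e7, bin_width = 5e5)
  mc_err <- 2 * sqrt(2 / n^2 / length(ld$decay$n_pairs))  # loose bound
  expect_lt(abs(mean(ld$decay$r2) - 1 / n), 10 * mc_err + 0.005)
  # flat curve: the background equals the overall mean level
  expect_lt(abs(ld$r2_bg - 1 / n), 0.01)
})

test_that("background LD reflects the decay plateau on mosaic genotypes", {
  cfg <- eqtl_scenario_config(seed = 3)
  cfg$n_genes <- 2L; cfg$cis_effects <- NULL; cfg$hotspot <- NULL
  pair <- simulate_genome_pair(cfg)
  gm <- simulate_population_genotypes(pair$truth, cfg)
  ld <- ld_background(gm$truth_dosage, gm$sites)
  expect_gt(ld$r2_bg, 0)
  expect_lt(ld$r2_bg, 0.5)
  expect_gt(ld$dist_bg, 2e5)
  # near-range LD well above background
  expect_gt(ld$decay$r2[1], ld$r2_bg + 0.2)
})

mk_results <- function(genes, svs, ps) {
  data.frame(gene_id = genes, sv_id = svs, beta = 1, se = 0.1, p = ps,
             stringsAsFactors = FALSE)
}

test_that("block construction chains linked significant SVs and classifies cis/trans", {
  set.seed(4)
  core <- rbinom(120, 2, 0.5)
  jitter_copy <- function() {
    x <- core; flip <- sample(120, 4); x[flip] <- 2 - x[flip]; x
  }
  d <- rbind(jitter_copy(), jitter_copy(), jitter_copy(),
             rbinom(120, 2, 0.5))
  rownames(d) <- paste0("s", 1:4)
  sv_sites <- data.frame(sv_id = paste0("s", 1:4), chrom = "chr1",
                         pos = c(100000, 120000, 140000, 9e6))
  genes <- data.frame(gene_id = c("gA", "gB"),
                      chrom = c("chr1", "chr2"),
                      tss = c(100000, 1e6), tes = c(105000, 1.01e6))
  res <- mk_results(rep("gA", 4), paste0("s", 1:4),
                    c(1e-9, 1e-8, 1e-8, 0.5))
  bl <- build_eqtl_blocks(res, d, sv_sites, genes, r2_bg = 0.205,
                          dist_bg = 1.94e6, sig_threshold = 1e-5)
  expect_equal(nrow(bl), 1)
  expect_equal(bl$n_svs, 3)
  expect_equal(bl$lead_sv, "s1")
  expect_equal(bl$class, "cis")   # lead at 140 kb? no: lead s1 at TSS
  # lead 35 kb from the TSS is still cis; a different chromosome is trans
  res2 <- mk_results(rep("gB", 4), paste0("s", 1:4),
                     c(1e-9, 1e-8, 1e-8, 0.5))
  bl2 <- build_eqtl_blocks(res2, d, sv_sites, genes, 0.205, 1.94e6, 1e-5)
  expect_equal(bl2$class, "trans")
  # two significant members only: no block
  res3 <- mk_results(rep("gA", 4), paste0("s", 1:4),
                     c(1e-9, 1e-8, 0.5, 0.5))
  expect_equal(nrow(build_eqtl_blocks(res3, d, sv_sites, genes, 0.205,
                                      1.94e6, 1e-5)), 0)
})

test_that("a lead SV within 50 kb of TSS or TES is cis, beyond is trans", {
  set.seed(11)
  d <- matrix(rbinom(3 * 100, 2, 0.5), 3, 100,
              dimnames = list(paste0("s", 1:3), NULL))
  d[2, ] <- ifelse(runif(100) < 0.95, d[1, ], 2 - d[1, ])
  d[3, ] <- ifelse(runif(100) < 0.95, d[1, ], 2 - d[1, ])
  sv_sites <- data.frame(sv_id = paste0("s", 1:3), chrom = "chr1",
                         pos = c(140000, 150000, 160000))
  res <- mk_results(rep("g", 3), paste0("s", 1:3), c(1e-9, 1e-7, 1e-7))
  genes_near <- data.frame(gene_id = "g", chrom = "chr1", tss = 100000,
                           tes = 105000)
  genes_far <- data.frame(gene_id = "g", chrom = "chr1", tss = 2e6,
                          tes = 2.05e6)
  expect_equal(build_eqtl_blocks(res, d, sv_sites, genes_near, 0.205,
                                 1.94e6, 1e-5)$class, "cis")
  expect_equal(build_eqtl_blocks(res, d, sv_sites, genes_far, 0.205,
                                 1.94e6, 1e-5)$class, "trans")
})

test_that("block construction is invariant to the input row order", {
  set.seed(8)
  d <- matrix(rbinom(6 * 100, 2, 0.5), 6, 100,
              dimnames = list(paste0("s", 1:6), NULL))
  for (i in 2:6) d[i, ] <- ifelse(runif(100) < 0.95, d[1, ], d[i, ])
  sv_sites <- data.frame(sv_id = paste0("s", 1:6), chrom = "chr1",
                         pos = seq(1e5, 6e5, by = 1e5))
  genes <- data.frame(gene_id = "g", chrom = "chr1", tss = 1e5, tes = 1.1e5)
  res <- mk_results(rep("g", 6), paste0("s", 1:6),
                    c(1e-9, 1e-8, 1e-7, 1e-8, 1e-7, 1e-6))
  b1 <- build_eqtl_blocks(res, d, sv_sites, genes, 0.205, 1.94e6, 1e-5)
  b2 <- build_eqtl_blocks(res[sample(6), ], d, sv_sites, genes, 0.205,
                          1.94e6, 1e-5)
  expect_identical(b1, b2)
  # empty input: empty output
  expect_equal(nrow(build_eqtl_blocks(res[0, ], d, sv_sites, genes, 0.205,
                                      1.94e6, 1e-5)), 0)
})
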