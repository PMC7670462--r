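# 1 SV shared by 10% of own group and 50% of donors -> site ratio 0.2;
# build a matrix realizing those shares exactly and check window logic.
test_that("sharing-ratio arithmetic and window thresholds follow the rule", {
  n_sp <- 10; n_mod <- 11  # focal excluded from own share -> 10 others
  mk <- function(pos, own_share_count, sp_share_count) {
    # focal accession is modern_01 with dosage 2 at every site
    row <- c(rep(2L, sp_share_count), rep(0L, n_sp - sp_share_count),
             2L,  # focal
             rep(2L, own_share_count), rep(0L, n_mod - 1 - own_share_count))
    row
  }
  # window [0,1e6): 2 SVs with ratio (1/10)/(5/10) = 0.2 -> emitted
  # window [2e6,3e6): 2 SVs with ratio (10/10)/(5/10) = 2 -> not emitted
  # window [4e6,5e6): 1 SV with low ratio -> below min_svs, not emitted
  dos <- rbind(mk(1, 1, 5), mk(2, 1, 5), mk(3, 10, 5), mk(4, 10, 5),
               mk(5, 1, 5))
  pos <- c(1e5, 2e5, 2.1e6, 2.2e6, 4.1e6)
  sites <- data.frame(sv_id = paste0("s", 1:5), chrom = "chr1", pos = pos,
                      end = pos + 10, sv_type = "deletion")
  groups <- setNames(c(rep("SP", n_sp), rep("modern", n_mod)),
                     c(paste0("sp", 1:n_sp), paste0("mod", 1:n_mod)))
  gm <- genotype_matrix(dos, sites, groups)
  seg <- introgression_scan(gm, focal_groups = "modern",
                            window = 1e6, step = 1e6,
                            chrom_lengths = c(chr1 = 5e6))
  foc <- seg[seg$accession == "mod1", ]
  expect_true(any(foc$start == 0))
  expect_equal(foc$mean_ratio[foc$start == 0], 0.2)
  expect_false(any(foc$start == 2e6))
  expect_false(any(foc$start == 4e6))
})

test_that("windows with mean ratio above the cutoff are not emitted", {
  # one window whose mean sits at 0.95
  n <- 21
  dos <- rbind(c(rep(2L, 10), rep(2L, 11)),   # ratio 1.0 everywhere
               c(rep(2L, 10), rep(2L, 11)))
  dos[1, 12:21] <- 0L  # focal keeps 2; 0 others share -> handled below
  sites <- data.frame(sv_id = c("s1", "s2"), chrom = "chr1",
                      pos = c(1e5, 2e5), end = c(1e5, 2e5) + 10,
                      sv_type = "deletion")
  groups <- setNames(c(rep("SP", 10), rep("modern", 11)),
                     c(paste0("sp", 1:10), paste0("m", 1:11)))
  gm <- genotype_matrix(dos, sites, groups)
  seg <- introgression_scan(gm, focal_groups = "modern", window = 1e6,
                            step = 1e6, ratio_max = 0.9,
                            chrom_lengths = c(chr1 = 1e6))
  # m1 at s1: own share 0, ratio 0; at s2: ratio (10/10)/1 = 1 -> mean 0.5
  m1 <- seg[seg$accession == "m1", ]
  expect_equal(m1$mean_ratio, 0.5)
  # the other moderns share everything: mean ratio ~1 -> absent
  expect_false(any(seg$accession == "m2"))
})

test_that("an empty donor group is an error", {
  gm <- toy_genotypes()
  gm$groups[] <- "modern"
  expect_error(introgression_scan(gm), "donor")
})

test_that("planted introgressions are recovered at the window level", {
  cfg <- introgression_scenario_config(seed = 8)
  pair <- simulate_genome_pair(cfg)
  gm <- simulate_population_genotypes(pair$truth, cfg)
  seg <- introgression_scan(gm, chrom_lengths = sapply(pair$genome_a,
                                                       nchar))
  tru <- unique(gm$introgressions$accession)
  win_starts <- seq(0, 10e6 - 1, by = 250e3)
  full <- win_starts[win_starts >= 3e6 & win_starts + 1e6 <= 5e6]
  overl <- win_starts[win_starts < 5e6 & win_starts + 1e6 > 3e6]
  det <- paste(seg$accession, seg$start)
  recall <- mean(as.vector(outer(tru, full, paste)) %in% det)
  precision <- mean(det %in% as.vector(outer(tru, overl, paste)))
  expect_gte(recall, 0.8)
  expect_gte(precision, 0.8)
})
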