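mk_blocks <- function(gene_ids, chrom, lead_pos, class = "trans") {
  data.frame(gene_id = gene_ids, chrom = chrom, start = lead_pos - 100,
             end = lead_pos + 100, n_svs = 3,
             lead_sv = paste0("sv_", seq_along(gene_ids)),
             lead_pos = lead_pos, lead_p = 1e-9, class = class,
             members = "", stringsAsFactors = FALSE)
}

test_that("a target pile-up in one window is a significant hotspot", {
  set.seed(1)
  lens <- list(chr1 = 100e6)
  # 30 of 40 targets led from one 50-kb window, the rest uniform
  pos <- c(runif(30, 10e6, 10e6 + 4e4), runif(10, 0, 100e6))
  bl <- mk_blocks(paste0("g", 1:40), "chr1", pos)
  hs <- detect_hotspots(bl, lens)
  expect_gte(nrow(hs), 1)
  top <- hs[which.max(hs$n_targets), ]
  expect_lt(top$adj_p, 0.05)
  expect_gte(top$n_targets, 28)
  expect_true(top$start <= 10e6 && top$end >= 10e6 + 4e4)
})

test_that("uniformly scattered targets rarely produce hotspots", {
  set.seed(2)
  lens <- list(chr1 = 100e6)
  n_sig <- replicate(10, {
    pos <- runif(40, 0, 100e6)
    nrow(detect_hotspots(mk_blocks(paste0("g", 1:40), "chr1", pos), lens))
  })
  n_windows <- length(seq(0, 100e6 - 1, by = 25e3))
  expect_lte(mean(n_sig), 0.05 * n_windows)
  expect_lte(median(n_sig), 1)
})

test_that("cis blocks and empty input yield no hotspot", {
  lens <- list(chr1 = 1e6)
  expect_equal(nrow(detect_hotspots(
    mk_blocks("g1", "chr1", 5e5, class = "cis"), lens)), 0)
  empty <- mk_blocks("g1", "chr1", 5e5)[0, ]
  expect_equal(nrow(detect_hotspots(empty, lens)), 0)
})

test_that("iGA enrichment matches the hypergeometric oracle", {
  ranked <- paste0("g", 1:20)
  # all 3 targets at the very top: min over prefixes includes the prefix of
  # size 3 holding all targets -> p = 1/choose(20, 3)
  p <- svdomest:::iga_min_hypergeom(ranked, c("g1", "g2", "g3"))
  expect_equal(p, 1 / choose(20, 3), tolerance = 1e-12)
  # brute-force oracle over every prefix for a scattered membership
  members <- c("g2", "g7", "g15")
  brute <- min(sapply(seq_along(ranked), function(n) {
    x <- sum(members %in% ranked[1:n])
    if (x == 0) return(1)
    phyper(x - 1, 3, 17, n, lower.tail = FALSE)
  }))
  expect_equal(svdomest:::iga_min_hypergeom(ranked, members), brute,
               tolerance = 1e-12)
})

test_that("a simulated regulator ranks first among window candidates", {
  set.seed(5)
  n_acc <- 120
  reg <- rnorm(n_acc)
  expr <- matrix(rnorm(40 * n_acc), 40, n_acc,
                 dimnames = list(paste0("g", 1:40), NULL))
  expr["g1", ] <- reg
  for (t in paste0("g", 11:20)) expr[t, ] <- expr[t, ] + 1.0 * reg
  genes <- data.frame(gene_id = paste0("g", 1:40), chrom = "chr1",
                      tss = seq(1e5, 4e6, length.out = 40))
  genes$tes <- genes$tss + 2000
  # hotspot window containing g1 and the unrelated g2
  genes$tss[2] <- genes$tss[1] + 5000; genes$tes[2] <- genes$tss[2] + 2000
  hs <- data.frame(chrom = "chr1", start = genes$tss[1] - 1e4,
                   end = genes$tss[1] + 2e4, n_targets = 10,
                   targets = paste(paste0("g", 11:20), collapse = ","),
                   adj_p = 1e-6, stringsAsFactors = FALSE)
  r <- rank_master_regulator(hs, expr, genes)
  expect_equal(r$candidate[1], "g1")
  expect_lt(r$iga_p[1], r$iga_p[r$candidate == "g2"])
  # a window holding exactly one expressed gene returns that gene
  hs1 <- hs; hs1$start <- genes$tss[40] - 100; hs1$end <- genes$tss[40] + 100
  expect_equal(rank_master_regulator(hs1, expr, genes)$candidate, "g40")
  hs_none <- hs; hs_none$start <- 9e6; hs_none$end <- 9.1e6
  expect_error(rank_master_regulator(hs_none, expr, genes), "no expressed")
})
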