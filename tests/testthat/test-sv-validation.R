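test_that("gap proximity filtering follows the <50 bp rule on both genomes", {
  svs <- rbind(mk_sv("s1", "deletion", 1000, 1100),
               mk_sv("s2", "deletion", 1000, 1100),
               mk_sv("s3", "deletion", 5000, 5100))
  gaps_near <- data.frame(chrom = "chr1", start = 1140, end = 1200)
  gaps_far <- data.frame(chrom = "chr1", start = 1200, end = 1300)
  expect_equal(filter_gap_proximity(svs[1, ], gaps_near, NULL)$id,
               character(0))                       # distance 40 < 50
  expect_equal(filter_gap_proximity(svs[2, ], gaps_far, NULL)$id, "s2")
  expect_identical(filter_gap_proximity(svs, NULL, NULL), svs)
  # gap on the other genome also removes
  expect_equal(nrow(filter_gap_proximity(svs[1, ], NULL, gaps_near)), 0)
  # spanning gap removes
  expect_equal(nrow(filter_gap_proximity(
    svs[1, ], data.frame(chrom = "chr1", start = 1050, end = 1060), NULL)), 0)
  # subset and order preserved
  out <- filter_gap_proximity(svs, gaps_near, NULL)
  expect_identical(out$id, "s3")
})

test_that("indel flank validation applies the 20% and 3-bp geometry rules", {
  hit <- function(flank, hs, he, ident = 99, len = 4000, ev = 1e-40)
    data.frame(flank = flank, hit_chrom = "chr1", hit_start = hs,
               hit_end = he, align_length = len, identity = ident,
               evalue = ev, stringsAsFactors = FALSE)
  ins <- mk_sv("i1", "insertion", 20000, 20000, size = 500,
               start_b = 20000, end_b = 20500)
  # hit distance 560 vs estimate 500: 12% < 20%
  hits <- rbind(hit("left", 15000, 20000), hit("right", 20560, 25560))
  expect_true(validate_indel_flanks(ins, hits, 500))
  # 25% discrepancy fails
  hits2 <- rbind(hit("left", 15000, 20000), hit("right", 20625, 25625))
  expect_false(validate_indel_flanks(ins, hits2, 500))
  del <- mk_sv("d1", "deletion", 30000, 30500, start_b = 30000,
               end_b = 30000)
  # flanks overlapping by 5 bp (>= 3) fail
  hd <- rbind(hit("left", 25000, 30000), hit("right", 29995, 34995))
  expect_false(validate_indel_flanks(del, hd, 500))
  hd2 <- rbind(hit("left", 25000, 30000), hit("right", 30001, 35001))
  expect_true(validate_indel_flanks(del, hd2, 500))
  # identity below 90% disqualifies regardless of geometry
  hd3 <- rbind(hit("left", 25000, 30000, ident = 85),
               hit("right", 30000, 35000))
  expect_false(validate_indel_flanks(del, hd3, 500))
  expect_false(validate_indel_flanks(del, hd3[0, ], 500))
  inv <- mk_sv("v1", "inversion", 100, 700)
  expect_error(validate_indel_flanks(inv, hd2, 500), "validate_inversion")
})

test_that("inversion validation needs >90% split reads or both callers", {
  inv <- mk_sv("v1", "inversion", 100, 700)
  bp <- function(s, t) data.frame(split_count = s, spanning_total = t)
  expect_true(validate_inversion(inv, bp(c(19, 46), c(20, 50)),
                                 "read_mapping_caller1"))
  expect_false(validate_inversion(inv, bp(c(8, 9), c(10, 10)),
                                  "read_mapping_caller1"))
  expect_true(validate_inversion(inv, bp(c(0, 0), c(10, 10)),
                                 c("read_mapping_caller1",
                                   "read_mapping_caller2")))
  # zero-total breakpoint with single-caller support: insufficient, FALSE
  expect_false(validate_inversion(inv, bp(c(19, 0), c(20, 0)),
                                  "read_mapping_caller2"))
  expect_error(validate_inversion(inv, bp(c(-1, 0), c(10, 10)), "x"))
})

test_that("repeat records convert to precise indels or are dropped", {
  rep1 <- mk_sv("r1", "repeat_contraction", 5000, 6000)
  prec <- mk_sv("p1", "deletion", 5200, 5700,
                sources = "read_mapping_caller1")
  out <- normalize_repeat_svs(rep1, prec)
  expect_equal(nrow(out), 1)
  expect_equal(out$sv_type, "deletion")
  expect_equal(c(out$start_a, out$end_a), c(5200, 5700))
  expect_true(grepl("genome_alignment", out$sources))
  # no precise match: dropped
  rep2 <- mk_sv("r2", "tandem_expansion", 9000, 9400)
  expect_equal(nrow(normalize_repeat_svs(rep2, prec)), 0)
  # simple records pass through unchanged
  del <- mk_sv("d1", "deletion", 100, 300)
  expect_identical(normalize_repeat_svs(del, prec)$id, "d1")
})

test_that("reciprocal-overlap merging combines, keeps set-1 coordinates and sources union", {
  a <- mk_sv("a1", "deletion", 100, 200, sources = "genome_alignment")
  b1 <- mk_sv("b1", "deletion", 120, 220,
              sources = "read_mapping_caller1")      # 80% reciprocal
  b2 <- mk_sv("b2", "deletion", 160, 400,
              sources = "read_mapping_caller1")      # 17% of second
  m <- merge_sv_sets(a, b1)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start_a, m$end_a), c(100, 200))
  expect_equal(m$sources, "genome_alignment,read_mapping_caller1")
  expect_equal(nrow(merge_sv_sets(a, b2)), 2)
  # disjoint records are both retained
  c1 <- mk_sv("c1", "deletion", 900, 1000)
  expect_equal(nrow(merge_sv_sets(a, c1)), 2)
  # insertions pair by breakpoint distance and size ratio
  i1 <- mk_sv("i1", "insertion", 500, 500, size = 100)
  i2 <- mk_sv("i2", "insertion", 550, 550, size = 90)
  i3 <- mk_sv("i3", "insertion", 700, 700, size = 100)
  expect_equal(nrow(merge_sv_sets(i1, i2)), 1)
  expect_equal(nrow(merge_sv_sets(i1, i3)), 2)
})

test_that("merging a set with itself is idempotent", {
  cfg <- tiny_sim(seed = 13)
  pair <- simulate_genome_pair(cfg)
  x <- pair$truth$svs
  x$sources <- "genome_alignment"
  m <- merge_sv_sets(x, x)
  expect_equal(nrow(m), nrow(x))
})

test_that("the validation pipeline recovers planted SVs with no false records", {
  for (seed in c(3, 17)) {
    cfg <- tiny_sim(seed = seed)
    pair <- simulate_genome_pair(cfg)
    cs <- simulate_sv_callsets(pair$truth, cfg)
    ref <- build_reference_sv_set(cs$assemblytics, cs$read_calls,
                                  cs$flank_hits, cs$inversion_evidence,
                                  cs$gaps_a, cs$gaps_b)
    tr <- pair$truth$svs
    matched <- vapply(seq_len(nrow(tr)), function(i)
      any(ref$chrom_a == tr$chrom_a[i] &
            abs(ref$start_a - tr$start_a[i]) <= 10 &
            abs(ref$size - tr$size[i]) <= 10), logical(1))
    false_rec <- vapply(seq_len(nrow(ref)), function(i)
      !any(tr$chrom_a == ref$chrom_a[i] &
             abs(tr$start_a - ref$start_a[i]) <= 10), logical(1))
    expect_gte(mean(matched), 0.95)
    expect_equal(sum(false_rec), 0)
    expect_true(all(ref$validated))
  }
})
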