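test_that("read-pair deduplication keys on the length-dependent prefix", {
  base <- strrep("ACGT", 40)  # 160 bp of sequence material
  p100 <- data.frame(
    left_seq = c(substr(base, 1, 100),
                 paste0(substr(base, 1, 94), "ACGTAC")),
    right_seq = substr(base, 21, 120), stringsAsFactors = FALSE)
  # identical over the first 90 bp of both mates, differing at base 95
  expect_equal(nrow(dedup_read_pairs(p100, 100)), 1)
  p_diff <- p100
  substr(p_diff$left_seq[2], 5, 5) <- "T"
  expect_equal(nrow(dedup_read_pairs(p_diff, 100)), 2)
  p150 <- data.frame(
    left_seq = c(substr(base, 1, 150),
                 paste0(substr(base, 1, 120), substr(base, 1, 30))),
    right_seq = substr(base, 11, 160), stringsAsFactors = FALSE)
  expect_equal(nrow(dedup_read_pairs(p150, 150)), 1)
  expect_warning(dedup_read_pairs(p100, 120), "unsupported")
})

test_that("empty alignments give all-zero evidence", {
  cfg <- tiny_sim(seed = 7)
  pair <- simulate_genome_pair(cfg)
  sv <- pair$truth$svs[pair$truth$svs$sv_type == "deletion", ][1, ]
  ev <- collect_evidence(svdomest:::empty_aln(), svdomest:::empty_aln(), sv)
  expect_equal(max(ev$split_present_bp1, ev$split_absent_bp1,
                   ev$span_present, ev$span_absent), 0)
  expect_equal(ev$covered_frac_2x, 0)
  expect_equal(call_genotype(ev), "MISSING")
})

test_that("SVs outside the reference are rejected by id", {
  cfg <- tiny_sim(seed = 7)
  pair <- simulate_genome_pair(cfg)
  sv <- pair$truth$svs[1, ]
  sv$end_a <- 1e9; sv$id <- "SVBAD"
  expect_error(collect_evidence(svdomest:::empty_aln(),
                                svdomest:::empty_aln(), sv,
                                ref_lengths = list(
                                  a = sapply(pair$genome_a, nchar),
                                  b = sapply(pair$genome_b, nchar))),
               "SVBAD")
})

test_that("genotype decision rules match the split-read and depth criteria", {
  base <- data.frame(sv_id = "s", accession = "a", sv_type = "inversion",
                     present_allele = "A", split_present_bp1 = 0,
                     split_present_bp2 = 0, split_absent_bp1 = 0,
                     split_absent_bp2 = 0, span_present = 0,
                     span_absent = 0, covered_frac_2x = NA_real_,
                     left_flank_frac = NA_real_,
                     right_flank_frac = NA_real_,
                     stringsAsFactors = FALSE)
  # inversion: >=3 split reads on the A orientation at both breakpoints
  inv <- base; inv$split_present_bp1 <- 4; inv$split_present_bp2 <- 5
  expect_equal(call_genotype(inv), "A_HOM")
  inv2 <- inv; inv2$split_present_bp2 <- 2
  expect_equal(call_genotype(inv2), "MISSING")  # one breakpoint under 3
  # deletion depth rule: segment uncovered, one flank covered
  del <- base; del$sv_type <- "deletion"
  del$covered_frac_2x <- 0.3; del$left_flank_frac <- 0.8
  del$right_flank_frac <- 0.2
  expect_equal(call_genotype(del), "B_HOM")
  # both-allele support: split reads for absence plus spanning coverage
  het <- del; het$split_absent_bp1 <- 4
  het$covered_frac_2x <- 0.9; het$span_present <- 5
  expect_equal(call_genotype(het), "HET")
  # purity: identical summaries give identical calls
  expect_equal(call_genotype(het), call_genotype(het))
})

test_that("matrix assembly drops under-genotyped accessions only", {
  ev_row <- function(sv, acc, covered, lf) {
    data.frame(sv_id = sv, accession = acc, sv_type = "deletion",
               present_allele = "A", split_present_bp1 = 0,
               split_present_bp2 = 0, split_absent_bp1 = 0,
               split_absent_bp2 = 0, span_present = 0, span_absent = 0,
               covered_frac_2x = covered, left_flank_frac = lf,
               right_flank_frac = 0, stringsAsFactors = FALSE)
  }
  svs <- sprintf("sv%02d", 1:10)
  # acc1: 10/10 called B_HOM; acc2: 4/10 called (exactly 40%); acc3: 3/10
  rows <- list()
  for (s in svs) rows[[length(rows) + 1]] <- ev_row(s, "acc1", 0.2, 0.9)
  for (i in 1:10) rows[[length(rows) + 1]] <-
    ev_row(svs[i], "acc2", if (i <= 4) 0.2 else 0.6, if (i <= 4) 0.9 else 0.3)
  for (i in 1:10) rows[[length(rows) + 1]] <-
    ev_row(svs[i], "acc3", if (i <= 3) 0.2 else 0.6, if (i <= 3) 0.9 else 0.3)
  ev <- do.call(rbind, rows)
  gm <- build_genotype_matrix(ev)
  expect_setequal(colnames(gm$dosage), c("acc1", "acc2"))
  expect_equal(gm$dropped, "acc3")
  # calls are never altered, only columns dropped
  gm_all <- build_genotype_matrix(ev, min_genotyped = 0)
  expect_identical(gm_all$dosage[, c("acc1", "acc2")], gm$dosage)
  expect_error(build_genotype_matrix(ev[0, ]), "empty")
  expect_error(build_genotype_matrix(rbind(ev, ev[1, ])), "duplicated")
})

test_that("concordance counts shared non-missing cells", {
  gm <- toy_genotypes()
  expect_equal(concordance(gm, gm), 1.0)
  gm2 <- gm
  # rows 1:3 and 5:6 are non-missing; flip one of four cells in a 2x2 view
  gm2$dosage[1, 1] <- 0L
  sub <- function(g, rows, cols) {
    g$dosage <- g$dosage[rows, cols, drop = FALSE]
    g$sites <- g$sites[rows, ]
    g$groups <- g$groups[cols]
    g
  }
  a <- sub(gm, 1:2, 1:2); b <- sub(gm2, 1:2, 1:2)
  expect_equal(concordance(a, b), 0.75)
  miss <- gm
  miss$dosage[] <- NA_integer_
  expect_error(concordance(miss, miss), "non-missing")
})

test_that("evidence-based calls recover simulated truth across SV types", {
  cfg <- tiny_sim(seed = 31, read_depth = 15)
  pair <- simulate_genome_pair(cfg)
  svs <- pair$truth$svs
  set.seed(42)
  n <- 30
  cases <- data.frame(sv = sample(nrow(svs), n, replace = TRUE),
                      g = sample(c("A_HOM", "B_HOM", "HET"), n,
                                 replace = TRUE))
  calls <- vapply(seq_len(n), function(i) {
    aln <- simulate_read_evidence(pair, svs[cases$sv[i], ], cases$g[i],
                                  cfg, accession = paste0("c", i))
    call_genotype(collect_evidence(aln$aln_a, aln$aln_b,
                                   svs[cases$sv[i], ]))
  }, character(1))
  expect_gte(mean(calls == cases$g), 0.9)
})
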