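# Independent oracles and small shared fixtures.

# Two-sided Fisher exact p by direct hypergeometric enumeration over all
# tables with the observed margins: sum of probabilities of tables whose
# point probability does not exceed the observed one (with the usual
# floating-point tie guard).
fisher_p_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c
  lo <- max(0, k - r2); hi <- min(k, r1)
  dens <- dhyper(lo:hi, r1, r2, k)
  sum(dens[dens <= dhyper(a, r1, r2, k) * (1 + 1e-7)])
}

# Tiny genome/SV scenario reused across read-evidence tests.
tiny_sim <- function(seed = 7, ...) {
  sim_config(seed = seed, n_chromosomes = 2L, chrom_length = 2e5,
             n_deletions = 4L, n_insertions = 3L, n_inversions = 2L,
             sv_size_range = c(40, 300), snp_rate = 1e-4,
             group_sizes = c(SP = 12L, SLC = 12L, heirloom = 12L,
                             modern = 12L), ...)
}

# A small hand-built genotype matrix: 6 SVs x 8 accessions in two groups.
toy_genotypes <- function() {
  dos <- matrix(c(2L, 2L, 1L, 0L, 0L, 0L, 0L, 0L,
                  2L, 2L, 2L, 2L, 0L, 0L, 0L, 0L,
                  0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L,
                  NA, NA, NA, NA, NA, NA, NA, NA,
                  2L, 0L, 2L, 0L, 2L, 0L, 2L, 0L,
                  1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L),
                nrow = 6, byrow = TRUE)
  sites <- data.frame(sv_id = paste0("sv", 1:6), chrom = "chr1",
                      pos = c(1e5, 2e5, 3e5, 4e5, 5e5, 6e5),
                      end = c(1e5, 2e5, 3e5, 4e5, 5e5, 6e5) + 100,
                      sv_type = "deletion", stringsAsFactors = FALSE)
  groups <- setNames(rep(c("SP", "SLC"), each = 4),
                     paste0("acc", 1:8))
  genotype_matrix(dos, sites, groups)
}

# Basic SV table builder for the validation tests.
mk_sv <- function(id, type, start, end, size = end - start, chrom = "chr1",
                  start_b = start, end_b = end, sources = "genome_alignment") {
  data.frame(id = id, sv_type = type, chrom_a = chrom, start_a = start,
             end_a = end, chrom_b = chrom, start_b = start_b,
             end_b = end_b, size = size, sources = sources,
             validated = FALSE, stringsAsFactors = FALSE)
}
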