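#' Simulate population SV genotypes across domestication stages
#'
#' Draws genotypes for every planted SV in every accession of a four-stage
#' population (SP wild progenitor, SLC early domesticate, heirloom, modern).
#' Haplotypes are mosaics of the two reference archetypes (all-A vs all-B)
#' with exponentially distributed segment lengths, which creates local
#' linkage disequilibrium decaying over `recomb_mean_segment` bp plus the
#' structure-induced background LD expected when groups with different
#' allele frequencies are pooled.  A per-locus flip probability
#' (`founder_flip` with SD `drift_sd`) keeps neighbouring loci from being
#' perfect copies and injects per-locus drift.  High homozygosity is
#' controlled by `inbreeding` (probability that an accession's two
#' haplotypes are identical).
#'
#' Selected loci are modeled as forced per-group target frequencies
#' (resampling that locus only, which mimics a completed sweep); planted
#' introgression blocks copy a random wild (SP) accession's genotypes into
#' the chosen fraction of focal-group accessions over the block interval.
#' Missing calls are injected at `missing_rate`.
#'
#' @param truth truth set from [simulate_genome_pair()].
#' @param config a [sim_config()] object.
#' @return A [genotype_matrix()] with observed (missing-injected) dosages.
#'   Additional elements carry the simulation truth: `truth_dosage`
#'   (complete dosage matrix), `introgressions` (data.frame of planted
#'   segments per accession), `selected` (the forced-frequency table).
#' @export
simulate_population_genotypes <- function(truth, config) {
  validate_sim_config(config)
  svs <- truth$svs
  if (!nrow(svs)) stop("truth set contains no SVs")
  set.seed(stage_seed(config, "population"))

  svs <- svs[order(svs$chrom_a, svs$start_a), , drop = FALSE]
  n_loci <- nrow(svs)
  groups_def <- config$group_sizes
  if (!is.null(config$selected_loci)) {
    zero <- names(groups_def)[groups_def == 0]
    if (length(zero) &&
        any(!is.na(as.matrix(config$selected_loci[, zero, drop = FALSE]))))
      stop("selected-locus trajectory given for empty group(s): ",
           paste(zero, collapse = ", "))
  }

  groups <- rep(names(groups_def), groups_def)
  acc_ids <- unlist(lapply(names(groups_def), function(g)
    sprintf("%s_%03d", g, seq_len(groups_def[[g]]))), use.names = FALSE)
  names(groups) <- acc_ids
  n_acc <- length(acc_ids)

  # per-locus flip probabilities, one draw per (locus, group)
  flip_p <- vapply(names(groups_def), function(g)
    pmin(pmax(config$founder_flip +
                stats::rnorm(n_loci, 0, config$drift_sd), 0), 0.49),
    numeric(n_loci))
  if (n_loci == 1) flip_p <- matrix(flip_p, nrow = 1,
                                    dimnames = list(NULL, names(groups_def)))

  # archetype probability solving  f_A = a(1-m) + (1-a) m  for a
  mbar <- config$founder_flip
  arch_a <- pmin(pmax((config$group_freq_a - mbar) /
                        max(1 - 2 * mbar, 1e-6), 0), 1)

  # switch probabilities between consecutive loci (within chromosome)
  chrom_rle <- rle(svs$chrom_a)
  blocks <- split(seq_len(n_loci), factor(svs$chrom_a,
                                          levels = chrom_rle$values))

  draw_haplotype <- function(g) {
    aB <- 1 - arch_a[[g]]          # archetype B probability
    alleleB <- integer(n_loci)
    for (idx in blocks) {
      len <- length(idx)
      pos <- svs$start_a[idx]
      if (len > 1) {
        p_sw <- 1 - exp(-diff(pos) / config$recomb_mean_segment)
        sw <- c(TRUE, stats::runif(len - 1) < p_sw)
      } else sw <- TRUE
      seg <- cumsum(sw)
      arch <- stats::rbinom(max(seg), 1, aB)
      alleleB[idx] <- arch[seg]
    }
    flips <- stats::runif(n_loci) < flip_p[, g]
    as.integer(xor(alleleB, flips))
  }

  dosage <- matrix(NA_integer_, n_loci, n_acc,
                   dimnames = list(svs$id, acc_ids))
  for (j in seq_len(n_acc)) {
    g <- groups[j]
    h1 <- draw_haplotype(g)
    h2 <- if (stats::runif(1) < config$inbreeding) h1 else draw_haplotype(g)
    dosage[, j] <- 2L - (h1 + h2)   # dosage of the A allele
  }

  # forced sweep targets
  sel <- config$selected_loci
  if (!is.null(sel)) {
    for (r in seq_len(nrow(sel))) {
      l <- sel$sv[r]
      if (l < 1 || l > n_loci) stop("selected locus index out of range: ", l)
      for (g in names(groups_def)) {
        t_a <- sel[[g]][r]
        if (is.na(t_a)) next
        cols <- which(groups == g)
        for (j in cols) {
          if (stats::runif(1) < config$inbreeding)
            dosage[l, j] <- 2L * stats::rbinom(1, 1, t_a)
          else
            dosage[l, j] <- stats::rbinom(1, 1, t_a) +
              stats::rbinom(1, 1, t_a)
        }
      }
    }
  }

  # planted introgressions: copy SP genotypes into focal accessions
  intro <- config$introgression_blocks
  intro_log <- data.frame(accession = character(), group = character(),
                          chrom = character(), start = numeric(),
                          end = numeric(), stringsAsFactors = FALSE)
  if (!is.null(intro) && nrow(intro)) {
    sp_cols <- which(groups == "SP")
    if (!length(sp_cols)) stop("introgression blocks require SP accessions")
    for (r in seq_len(nrow(intro))) {
      g <- intro$group[r]
      cols <- which(groups == g)
      n_take <- max(1L, round(intro$frac[r] * length(cols)))
      take <- sample(cols, n_take)
      loci <- which(svs$chrom_a == intro$chrom[r] &
                      svs$start_a >= intro$start[r] &
                      svs$start_a < intro$end[r])
      # donors drawn among the most wild-allele-rich SP accessions over the
      # block: introgressed material carries wild-specific alleles (a
      # segment identical to the cultivar haplotype would be undetectable
      # and would not have been worth introgressing)
      a_load <- colSums(dosage[loci, sp_cols, drop = FALSE])
      donor_pool <- sp_cols[order(-a_load)][seq_len(min(5L, length(sp_cols)))]
      for (j in take) {
        donor <- sample(donor_pool, 1L)
        if (length(loci)) dosage[loci, j] <- dosage[loci, donor]
        intro_log <- rbind(intro_log, data.frame(
          accession = acc_ids[j], group = g, chrom = intro$chrom[r],
          start = intro$start[r], end = intro$end[r],
          stringsAsFactors = FALSE))
      }
    }
  }

  observed <- dosage
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(length(dosage)) < config$missing_rate,
                   nrow = n_loci)
    observed[miss] <- NA_integer_
  }

  sites <- data.frame(sv_id = svs$id, chrom = svs$chrom_a,
                      pos = svs$start_a, end = svs$end_a,
                      sv_type = svs$sv_type, stringsAsFactors = FALSE)
  gm <- genotype_matrix(observed, sites, groups)
  gm$truth_dosage <- dosage
  gm$introgressions <- intro_log
  gm$selected <- sel
  gm
}

#' Realized A-allele frequencies from a dosage matrix
#'
#' Convenience used by simulator invariant checks: frequency =
#' (2 x A-hom + het) / (2 x called accessions), per locus.
#'
#' @param dosage matrix of A-allele dosages (rows = SVs).
#' @param cols optional column subset.
#' @return numeric vector of per-locus A frequencies (NaN where no calls).
#' @export
realized_freq_a <- function(dosage, cols = NULL) {
  if (!is.null(cols)) dosage <- dosage[, cols, drop = FALSE]
  rowSums(dosage, na.rm = TRUE) / (2 * rowSums(!is.na(dosage)))
}
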