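#' Per-group allele counts and frequencies
#'
#' For each SV and each population group, counts A and B alleles over the
#' non-missing calls (a homozygote contributes two copies of its allele, a
#' heterozygote one of each) and reports the A-allele frequency.  Groups
#' with no called accession at an SV get an NA frequency.
#'
#' @param gm a [genotype_matrix()].
#' @param groups_order optional group ordering; defaults to the canonical
#'   domestication-stage order restricted to the groups present.
#' @return data.frame with columns `sv_id`, `group`, `n_a`, `n_b`, `freq_a`.
#' @export
group_allele_frequencies <- function(gm, groups_order = NULL) {
  if (is.null(groups_order))
    groups_order <- intersect(valid_groups(), unique(gm$groups))
  out <- lapply(groups_order, function(g) {
    cols <- which(gm$groups == g)
    d <- gm$dosage[, cols, drop = FALSE]
    n_a <- rowSums(d, na.rm = TRUE)
    n_tot <- 2 * rowSums(!is.na(d))
    data.frame(sv_id = rownames(gm$dosage), group = g,
               n_a = n_a, n_b = n_tot - n_a,
               freq_a = ifelse(n_tot > 0, n_a / n_tot, NA_real_),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Fisher's exact selection scan between two domestication stages
#'
#' Tests, per SV, the 2x2 allele-count table between two groups with a
#' two-tailed Fisher's exact test, applies Bonferroni correction over the
#' number of SVs tested in this pair, and flags SVs whose corrected P falls
#' below `sel_p` as under selection.  SVs with a zero-margin table (a group
#' entirely missing) are skipped and reported in the `skipped` attribute.
#'
#' @param freqs output of [group_allele_frequencies()].
#' @param pair character(2): the compared groups, e.g. `c("SP", "SLC")` for
#'   domestication, `c("SLC", "heirloom")` for improvement.
#' @param sel_p corrected-P selection cutoff.
#' @param m Bonferroni denominator; defaults to the number of SVs tested in
#'   this pair (settable to a genome-wide test count instead).
#' @return data.frame with `sv_id`, `pair`, `p`, `p_corrected`, `direction`
#'   (`A_down` when the A frequency decreases from `pair[1]` to `pair[2]`),
#'   `selected`.
#' @export
fisher_selection_scan <- function(freqs, pair, sel_p = 0.001, m = NULL) {
  f1 <- freqs[freqs$group == pair[1], ]
  f2 <- freqs[freqs$group == pair[2], ]
  stopifnot(nrow(f1) == nrow(f2), all(f1$sv_id == f2$sv_id))
  ok <- (f1$n_a + f1$n_b) > 0 & (f2$n_a + f2$n_b) > 0
  skipped <- f1$sv_id[!ok]
  if (!any(ok)) stop("no SV with called alleles in both groups")
  a1 <- f1$n_a[ok]; b1 <- f1$n_b[ok]
  a2 <- f2$n_a[ok]; b2 <- f2$n_b[ok]
  p <- vapply(seq_along(a1), function(i)
    stats::fisher.test(matrix(c(a1[i], b1[i], a2[i], b2[i]), nrow = 2,
                              byrow = TRUE))$p.value, numeric(1))
  if (is.null(m)) m <- length(p)
  res <- data.frame(
    sv_id = f1$sv_id[ok],
    pair = paste(pair, collapse = "->"),
    p = p,
    p_corrected = pmin(1, p * m),
    direction = ifelse(f2$freq_a[ok] < f1$freq_a[ok], "A_down", "A_up"),
    stringsAsFactors = FALSE)
  res$selected <- res$p_corrected < sel_p
  attr(res, "skipped") <- skipped
  res
}

#' Per-accession genotype composition
#'
#' Fractions of SV loci with each genotype state in every accession (the
#' quantity summarized per group in stage-composition box plots).  The four
#' fractions sum to one.
#'
#' @param gm a [genotype_matrix()].
#' @return data.frame with `accession`, `group`, `f_a_hom`, `f_het`,
#'   `f_b_hom`, `f_missing`.
#' @export
genotype_composition <- function(gm) {
  if (!nrow(gm$dosage)) stop("empty genotype matrix")
  d <- gm$dosage
  n <- nrow(d)
  data.frame(
    accession = colnames(d),
    group = unname(gm$groups),
    f_a_hom = colSums(d == 2L, na.rm = TRUE) / n,
    f_het = colSums(d == 1L, na.rm = TRUE) / n,
    f_b_hom = colSums(d == 0L, na.rm = TRUE) / n,
    f_missing = colSums(is.na(d)) / n,
    stringsAsFactors = FALSE, row.names = NULL)
}
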