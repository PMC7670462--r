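#' Windowed nucleotide diversity and Weir-Cockerham F_ST
#'
#' Computes, in sliding windows (default 1000-kb windows, 250-kb step),
#' per-group nucleotide diversity and pairwise F_ST over the biallelic
#' sites of a genotype matrix (SVs, SNPs, or both).
#'
#' Per-site diversity uses the small-sample-corrected heterozygosity
#' `2 p (1-p) n/(n-1)` (n = sampled allele copies); window diversity is the
#' sum over sites divided by the window length.  F_ST is the two-population
#' Weir-Cockerham estimator aggregated per window as a ratio of averages
#' (sum of among-population components over sum of total components), the
#' convention of the standard VCF windowed-F_ST tools; negative estimates
#' are reported unclipped.
#'
#' @param gm a [genotype_matrix()] with `chrom` and `pos` in its sites.
#' @param window,step window and step sizes in bp.
#' @param chrom_lengths optional named chromosome lengths; windows otherwise
#'   extend to the last variant position.
#' @param groups_order groups to include (default: all present, canonical
#'   order); F_ST is computed for every pair.
#' @return data.frame with one row per (chrom, window): `chrom`, `start`,
#'   `end` (0-based half-open), `n_variants`, one `pi_<group>` column per
#'   group and one `fst_<g1>_<g2>` column per pair.  Empty windows carry NA
#'   statistics and a zero variant count.
#' @export
windowed_diversity_fst <- function(gm, window = 1e6, step = 250e3,
                                   chrom_lengths = NULL,
                                   groups_order = NULL) {
  if (is.null(groups_order))
    groups_order <- intersect(valid_groups(), unique(gm$groups))
  sites <- gm$sites
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, ]
  d <- gm$dosage[ord, , drop = FALSE]

  # per-site per-group summaries
  stat <- lapply(groups_order, function(g) {
    cols <- which(gm$groups == g)
    dg <- d[, cols, drop = FALSE]
    called <- rowSums(!is.na(dg))
    n <- 2 * called
    p <- ifelse(n > 0, rowSums(dg, na.rm = TRUE) / n, NA_real_)
    h <- ifelse(called > 0,
                rowSums(dg == 1L, na.rm = TRUE) / called, NA_real_)
    pi_site <- ifelse(n > 1, 2 * p * (1 - p) * n / (n - 1), NA_real_)
    list(n_ind = called, p = p, h = h, pi = pi_site)
  })
  names(stat) <- groups_order
  pairs <- if (length(groups_order) > 1)
    utils::combn(groups_order, 2, simplify = FALSE) else list()

  # per-site Weir-Cockerham variance components for each pair
  wc <- lapply(pairs, function(pr) {
    s1 <- stat[[pr[1]]]; s2 <- stat[[pr[2]]]
    weir_cockerham_site(s1$n_ind, s1$p, s1$h, s2$n_ind, s2$p, s2$h)
  })

  out <- list()
  for (ch in unique(sites$chrom)) {
    in_ch <- which(sites$chrom == ch)
    pos <- sites$pos[in_ch]
    len <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]] else
      max(pos) + 1
    starts <- seq(0, max(0, len - 1), by = step)
    for (ws in starts) {
      we <- min(ws + window, len)
      idx <- in_ch[pos >= ws & pos < we]
      row <- data.frame(chrom = ch, start = ws, end = we,
                        n_variants = length(idx),
                        stringsAsFactors = FALSE)
      for (g in groups_order)
        row[[paste0("pi_", g)]] <- if (length(idx))
          sum(stat[[g]]$pi[idx], na.rm = TRUE) / (we - ws) else NA_real_
      for (k in seq_along(pairs)) {
        nm <- paste0("fst_", pairs[[k]][1], "_", pairs[[k]][2])
        if (length(idx)) {
          num <- sum(wc[[k]]$a[idx], na.rm = TRUE)
          den <- sum(wc[[k]]$abc[idx], na.rm = TRUE)
          row[[nm]] <- if (den > 0) num / den else NA_real_
        } else row[[nm]] <- NA_real_
      }
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Two-population Weir & Cockerham (1984) per-site components.
# n1, n2: diploid sample sizes; p1, p2: allele frequencies; h1, h2:
# observed heterozygote frequencies.  Returns the among-population
# component `a` and the total `a + b + c` per site (NA when undefined).
weir_cockerham_site <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  ok <- !is.na(p1) & !is.na(p2) & n1 > 0 & n2 > 0 & (n1 + n2) > 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r -
       hbar * (2 * nbar - 1) / (4 * nbar))
  c_ <- hbar / 2
  a[!ok] <- NA_real_
  tot <- a + b + c_
  tot[!ok] <- NA_real_
  list(a = a, abc = tot)
}
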