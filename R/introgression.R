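#' Scan cultivated accessions for wild (donor) introgressions
#'
#' For each accession of the focal groups, and each SV it is genotyped at,
#' the fraction of accessions sharing its exact genotype state is computed
#' in its own group (excluding the accession itself) and in the donor
#' group; the site ratio is own-group sharing over donor-group sharing.
#' A genomic window whose mean ratio over the accession's sites is at most
#' `ratio_max` and which contains at least `min_svs` such sites is reported
#' as an introgression: the accession's genotypes there look like the donor
#' group rather than its own.  Sites where the donor group never shows the
#' genotype (zero sharing) are skipped for that accession; exact state
#' matching is used (a heterozygote matches only heterozygotes) and missing
#' calls are excluded throughout.
#'
#' @param gm a [genotype_matrix()].
#' @param focal_groups groups to scan (default heirloom and modern).
#' @param donor_group donor group (default SP).
#' @param window,step window and step in bp.
#' @param ratio_max maximum mean sharing ratio.
#' @param min_svs minimum qualifying SVs per window.
#' @param chrom_lengths optional named chromosome lengths.
#' @return data.frame with `accession`, `group`, `chrom`, `start`, `end`,
#'   `mean_ratio`, `n_svs`.
#' @export
introgression_scan <- function(gm, focal_groups = c("heirloom", "modern"),
                               donor_group = "SP",
                               window = 1e6, step = 250e3,
                               ratio_max = 0.9, min_svs = 2,
                               chrom_lengths = NULL) {
  donor_cols <- which(gm$groups == donor_group)
  if (!length(donor_cols)) stop("donor group is empty")
  d <- gm$dosage
  sites <- gm$sites

  # per-site, per-state share counts for donor and each focal group
  state_counts <- function(cols) {
    dg <- d[, cols, drop = FALSE]
    list(cnt = vapply(0:2, function(s) rowSums(dg == s, na.rm = TRUE),
                      numeric(nrow(d))),
         called = rowSums(!is.na(dg)))
  }
  donor <- state_counts(donor_cols)
  donor_share <- donor$cnt / pmax(donor$called, 1)
  donor_share[donor$called == 0, ] <- NA

  out <- list()
  for (g in intersect(focal_groups, unique(gm$groups))) {
    cols <- which(gm$groups == g)
    own <- state_counts(cols)
    for (j in cols) {
      s_j <- d[, j]
      has <- !is.na(s_j)
      idx <- which(has)
      st <- s_j[idx] + 1L
      n_others <- own$called[idx] - 1L
      own_share <- (own$cnt[cbind(idx, st)] - 1L) / pmax(n_others, 1)
      own_share[n_others <= 0] <- NA
      dshare <- donor_share[cbind(idx, st)]
      ratio <- own_share / dshare
      usable <- !is.na(ratio) & is.finite(ratio) & dshare > 0
      idx <- idx[usable]; ratio <- ratio[usable]
      if (!length(idx)) next
      acc_sites <- data.frame(chrom = sites$chrom[idx],
                              pos = sites$pos[idx], ratio = ratio)
      for (ch in unique(acc_sites$chrom)) {
        sub <- acc_sites[acc_sites$chrom == ch, ]
        len <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]] else
          max(sub$pos) + 1
        starts <- seq(0, max(0, len - 1), by = step)
        for (ws in starts) {
          we <- min(ws + window, len)
          in_w <- sub$pos >= ws & sub$pos < we
          if (sum(in_w) >= min_svs) {
            mr <- mean(sub$ratio[in_w])
            if (mr <= ratio_max)
              out[[length(out) + 1L]] <- data.frame(
                accession = colnames(d)[j], group = g, chrom = ch,
                start = ws, end = we, mean_ratio = mr,
                n_svs = sum(in_w), stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(accession = character(), group = character(),
                      chrom = character(), start = numeric(),
                      end = numeric(), mean_ratio = numeric(),
                      n_svs = integer(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
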