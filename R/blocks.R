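#' Build LD-clustered eQTL blocks and classify them cis/trans
#'
#' For each gene, its significant SVs (association p below `sig_threshold`)
#' are sorted along the genome and chained left to right: two adjacent
#' significant SVs join the same block when their pairwise r-squared
#' exceeds the background LD level and their distance is below the
#' background LD distance.  Chains with at least `min_svs` members become
#' candidate eQTL blocks, summarized by the lead SV (smallest p, leftmost
#' on ties).  A block is cis when its lead SV lies within `cis_window` of
#' the gene's transcription start or stop site on the same chromosome,
#' trans otherwise.  The result does not depend on the input row order.
#'
#' @param results association results (`gene_id`, `sv_id`, `p`).
#' @param dosages sites x accessions dosage matrix (rownames = sv ids),
#'   used for pairwise r-squared.
#' @param sv_sites data.frame `sv_id`, `chrom`, `pos`.
#' @param genes data.frame `gene_id`, `chrom`, `tss`, `tes`.
#' @param r2_bg,dist_bg background LD level and distance (bp), e.g. from
#'   [ld_background()].
#' @param sig_threshold significance cutoff on p.
#' @param min_svs minimum member SVs per block.
#' @param cis_window cis distance in bp from TSS or TES.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `n_svs`,
#'   `lead_sv`, `lead_pos`, `lead_p`, `class`, `members`.
#' @export
build_eqtl_blocks <- function(results, dosages, sv_sites, genes,
                              r2_bg = 0.205, dist_bg = 1.94e6,
                              sig_threshold, min_svs = 3,
                              cis_window = 50e3) {
  sig <- results[results$p < sig_threshold, , drop = FALSE]
  empty <- data.frame(gene_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_svs = integer(), lead_sv = character(),
                      lead_pos = numeric(), lead_p = numeric(),
                      class = character(), members = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(sig)) return(empty)
  pos_of <- stats::setNames(sv_sites$pos, sv_sites$sv_id)
  chrom_of <- stats::setNames(sv_sites$chrom, sv_sites$sv_id)

  out <- list()
  for (g in sort(unique(sig$gene_id))) {
    rg <- sig[sig$gene_id == g, , drop = FALSE]
    rg$chrom <- chrom_of[rg$sv_id]
    rg$pos <- pos_of[rg$sv_id]
    rg <- rg[order(rg$chrom, rg$pos, rg$sv_id), , drop = FALSE]
    if (!nrow(rg)) next
    block_id <- integer(nrow(rg))
    block_id[1] <- 1L
    for (i in seq_len(nrow(rg) - 1)) {
      same <- rg$chrom[i + 1] == rg$chrom[i] &&
        (rg$pos[i + 1] - rg$pos[i]) < dist_bg &&
        pair_r2(dosages[rg$sv_id[i], ], dosages[rg$sv_id[i + 1], ]) > r2_bg
      block_id[i + 1] <- if (same) block_id[i] else block_id[i] + 1L
    }
    gene_row <- genes[genes$gene_id == g, ]
    for (b in unique(block_id)) {
      mb <- rg[block_id == b, , drop = FALSE]
      if (nrow(mb) < min_svs) next
      lead <- mb[order(mb$p, mb$pos), ][1, ]
      cls <- "trans"
      if (nrow(gene_row) && !is.na(gene_row$chrom) &&
          lead$chrom == gene_row$chrom) {
        dtss <- min(abs(lead$pos - gene_row$tss),
                    abs(lead$pos - gene_row$tes))
        if (dtss <= cis_window) cls <- "cis"
      }
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g, chrom = mb$chrom[1], start = min(mb$pos),
        end = max(mb$pos), n_svs = nrow(mb), lead_sv = lead$sv_id,
        lead_pos = lead$pos, lead_p = lead$p, class = cls,
        members = paste(mb$sv_id, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(empty)
  res <- res[order(res$gene_id, res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
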