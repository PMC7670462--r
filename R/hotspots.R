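#' Detect trans-eQTL hotspots
#'
#' Slides 50-kb windows across the genome and counts, per window, the
#' distinct target genes whose trans-eQTL lead SV falls inside.  Window
#' counts are tested against a one-sided Poisson tail with the genome-wide
#' mean lead density as expectation, adjusted across all windows by
#' Benjamini-Hochberg; overlapping significant windows are merged into
#' hotspots carrying the union of their target genes.
#'
#' @param blocks eQTL block table from [build_eqtl_blocks()]; only rows
#'   with `class == "trans"` are used.
#' @param chrom_lengths named chromosome lengths in bp.
#' @param window window size in bp.
#' @param step step size in bp (default half window).
#' @param adj_p_max adjusted-P cutoff.
#' @return data.frame with `chrom`, `start`, `end`, `n_targets`,
#'   `targets` (comma-separated gene ids), `adj_p`.
#' @export
detect_hotspots <- function(blocks, chrom_lengths, window = 50e3,
                            step = window / 2, adj_p_max = 0.05) {
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_targets = integer(),
                      targets = character(), adj_p = numeric(),
                      stringsAsFactors = FALSE)
  tr <- blocks[blocks$class == "trans", , drop = FALSE]
  tr <- tr[!duplicated(paste(tr$gene_id, tr$chrom, tr$lead_pos)), ,
           drop = FALSE]
  if (!nrow(tr)) return(empty)
  total_len <- sum(unlist(chrom_lengths))
  lambda <- nrow(tr) * window / total_len

  rows <- list()
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, max(0, len - 1), by = step)
    in_ch <- tr[tr$chrom == ch, , drop = FALSE]
    for (ws in starts) {
      we <- min(ws + window, len)
      hit <- in_ch$lead_pos >= ws & in_ch$lead_pos < we
      genes <- unique(in_ch$gene_id[hit])
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = ws, end = we, n_targets = length(genes),
        targets = paste(genes, collapse = ","),
        p = stats::ppois(length(genes) - 1, lambda, lower.tail = FALSE),
        stringsAsFactors = FALSE)
    }
  }
  win <- do.call(rbind, rows)
  win$adj_p <- stats::p.adjust(win$p, method = "BH")
  sig <- win[win$adj_p < adj_p_max & win$n_targets > 0, , drop = FALSE]
  if (!nrow(sig)) return(empty)

  # merge overlapping significant windows per chromosome
  sig <- sig[order(sig$chrom, sig$start), , drop = FALSE]
  merged <- list()
  cur <- sig[1, ]
  flush <- function(cur) {
    genes <- unique(unlist(strsplit(cur$targets, ",")))
    data.frame(chrom = cur$chrom, start = cur$start, end = cur$end,
               n_targets = length(genes),
               targets = paste(genes, collapse = ","),
               adj_p = cur$adj_p, stringsAsFactors = FALSE)
  }
  if (nrow(sig) > 1) {
    for (i in 2:nrow(sig)) {
      r <- sig[i, ]
      if (r$chrom == cur$chrom && r$start <= cur$end) {
        cur$end <- max(cur$end, r$end)
        cur$targets <- paste(cur$targets, r$targets, sep = ",")
        cur$adj_p <- min(cur$adj_p, r$adj_p)
      } else {
        merged[[length(merged) + 1L]] <- flush(cur)
        cur <- r
      }
    }
  }
  merged[[length(merged) + 1L]] <- flush(cur)
  res <- do.call(rbind, merged)
  rownames(res) <- NULL
  res
}

#' Rank candidate master regulators of a trans-eQTL hotspot
#'
#' For every gene located inside the hotspot window, all expressed genes
#' are ranked by absolute Pearson correlation with that candidate, and the
#' enrichment of the hotspot's target genes near the top of the ranking is
#' scored by the iterative-group-analysis statistic: the minimum, over
#' ranking prefixes ending at a target, of the hypergeometric tail
#' probability of seeing that many targets so high.  Candidates are
#' returned ordered by this enrichment; the top row is the proposed master
#' regulator.
#'
#' @param hotspot one row of the [detect_hotspots()] table.
#' @param expr genes x accessions expression matrix (FPKM scale is fine;
#'   correlations are scale-free).
#' @param genes gene coordinate table (`gene_id`, `chrom`, `tss`, `tes`).
#' @return data.frame `candidate`, `iga_p`, `n_targets`, ordered by
#'   increasing `iga_p`.
#' @export
rank_master_regulator <- function(hotspot, expr, genes) {
  inside <- genes$chrom == hotspot$chrom &
    genes$tss < hotspot$end & genes$tes >= hotspot$start
  cand <- intersect(genes$gene_id[inside], rownames(expr))
  if (!length(cand)) stop("no expressed gene inside the hotspot window")
  targets <- unlist(strsplit(hotspot$targets, ","))
  if (length(cand) == 1 && !length(intersect(targets, rownames(expr))))
    return(data.frame(candidate = cand, iga_p = NA_real_, n_targets = 0L,
                      stringsAsFactors = FALSE))
  ex <- t(expr)
  out <- lapply(cand, function(cg) {
    r <- as.numeric(stats::cor(ex[, cg], ex))
    names(r) <- colnames(ex)
    r <- r[setdiff(names(r), cg)]
    ranked <- names(sort(-abs(r)))
    hits <- intersect(targets, ranked)
    data.frame(candidate = cg,
               iga_p = iga_min_hypergeom(ranked, hits),
               n_targets = length(hits), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$iga_p, res$candidate), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Minimal hypergeometric tail over ranking prefixes ending at group
# members (the iterative-group-analysis "PC-value").
iga_min_hypergeom <- function(ranked, members) {
  N <- length(ranked)
  t_n <- length(members)
  if (t_n == 0) return(1)
  pos <- sort(match(members, ranked))
  p <- vapply(seq_along(pos), function(i)
    stats::phyper(i - 1, t_n, N - t_n, pos[i], lower.tail = FALSE),
    numeric(1))
  min(p)
}
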