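#' Normalize an expression matrix for association mapping
#'
#' Three-step normalization: (1) convert raw fragment counts to FPKM
#' (`count * 1e9 / (gene_length * library_size)`) unless FPKM is supplied
#' directly; (2) drop genes with a median FPKM of zero, then drop accessions
#' lying more than `pc_sd_limit` standard deviations from the mean on any of
#' the first `n_pcs` principal components of the FPKM matrix; (3) transform
#' each gene to normal quantiles (rank-based, mid-ranks for ties), giving
#' every gene a standard-normal-shaped expression vector.
#'
#' @param counts genes x accessions matrix of raw fragment counts (or NULL
#'   if `fpkm` is given).
#' @param gene_lengths named or aligned vector of gene lengths in bp.
#' @param lib_sizes per-accession library sizes; defaults to column sums of
#'   `counts`.
#' @param fpkm genes x accessions FPKM matrix, bypassing step 1.
#' @param pc_sd_limit outlier cutoff in SDs on each inspected component.
#' @param n_pcs number of leading components inspected.
#' @return list with `fpkm` (filtered), `normalized` (quantile-normal),
#'   `dropped_genes`, `dropped_accessions`, `stage = "qq_normalized"`.
#' @export
normalize_expression <- function(counts = NULL, gene_lengths = NULL,
                                 lib_sizes = NULL, fpkm = NULL,
                                 pc_sd_limit = 2.5, n_pcs = 3) {
  if (is.null(fpkm)) {
    if (is.null(counts) || is.null(gene_lengths))
      stop("provide either fpkm or counts + gene_lengths")
    if (any(counts < 0)) stop("counts must be non-negative")
    if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
    fpkm <- counts * 1e9 /
      (matrix(gene_lengths, nrow(counts), ncol(counts)) *
         matrix(lib_sizes, nrow(counts), ncol(counts), byrow = TRUE))
    dimnames(fpkm) <- dimnames(counts)
  }
  med <- apply(fpkm, 1, stats::median)
  dropped_genes <- rownames(fpkm)[med == 0]
  fpkm <- fpkm[med > 0, , drop = FALSE]
  if (!nrow(fpkm)) stop("no gene left after the median-zero filter")

  pc <- stats::prcomp(t(fpkm), center = TRUE, scale. = FALSE)
  k <- min(n_pcs, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  out_acc <- rep(FALSE, ncol(fpkm))
  for (i in seq_len(k)) {
    z <- scores[, i]
    out_acc <- out_acc | abs(z - mean(z)) > pc_sd_limit * stats::sd(z)
  }
  dropped_accessions <- colnames(fpkm)[out_acc]
  fpkm <- fpkm[, !out_acc, drop = FALSE]
  if (ncol(fpkm) < 4) stop("fewer than 4 accessions left after filtering")

  normalized <- t(apply(fpkm, 1, quantile_normalize))
  dimnames(normalized) <- dimnames(fpkm)
  list(fpkm = fpkm, normalized = normalized,
       dropped_genes = dropped_genes,
       dropped_accessions = dropped_accessions,
       stage = "qq_normalized")
}

# Rank-to-normal-quantile transform; mid-ranks for ties, offsets matching
# the classical normal-scores plotting positions.
quantile_normalize <- function(x) {
  n <- length(x)
  a <- if (n <= 10) 3 / 8 else 0.5
  stats::qnorm((rank(x, ties.method = "average") - a) / (n + 1 - 2 * a))
}

#' Hidden expression factors as covariates
#'
#' Principal components of the normalized expression matrix used as proxies
#' for hidden/confounding expression factors: the leading `k` orthogonal
#' directions of variation across accessions, returned unit-normalized as
#' per-accession covariates.
#'
#' Technical confounders (batch, library depth, ...) load broadly across
#' the transcriptome, whereas a genetically driven co-expression module
#' concentrates its loadings on its member genes; correcting for the
#' latter erases exactly the trans signals a hotspot scan looks for.  With
#' `drop_concentrated = TRUE`, components whose squared loadings
#' concentrate more than `max_share` on the top `top_frac` of genes are
#' skipped before taking the first `k` factors.
#'
#' @param normalized genes x accessions matrix (quantile-normalized).
#' @param k number of factors (default 20).
#' @param drop_concentrated skip module-like components (see above).
#' @param top_frac,max_share concentration rule: a component is module-like
#'   when the top `top_frac` of genes carry more than `max_share` of its
#'   squared loadings.
#' @return accessions x k matrix of factor scores (columns orthogonal,
#'   unit norm); zero columns when `k = 0`.
#' @export
derive_hidden_factors <- function(normalized, k = 20,
                                  drop_concentrated = FALSE,
                                  top_frac = 0.05, max_share = 0.5) {
  n_acc <- ncol(normalized)
  if (k >= n_acc) stop("k must be smaller than the number of accessions")
  if (k == 0)
    return(matrix(numeric(0), n_acc, 0,
                  dimnames = list(colnames(normalized), NULL)))
  pc <- stats::prcomp(t(normalized), center = TRUE, scale. = FALSE)
  take <- seq_len(ncol(pc$x))
  if (drop_concentrated) {
    n_top <- max(1L, ceiling(top_frac * nrow(normalized)))
    share <- apply(pc$rotation, 2, function(l) {
      l2 <- sort(l^2, decreasing = TRUE)
      sum(l2[seq_len(n_top)]) / sum(l2)
    })
    take <- take[share <= max_share]
  }
  k <- min(k, length(take))
  if (k == 0)
    return(matrix(numeric(0), n_acc, 0,
                  dimnames = list(colnames(normalized), NULL)))
  f <- pc$x[, take[seq_len(k)], drop = FALSE]
  f <- sweep(f, 2, sqrt(colSums(f^2)), "/")
  colnames(f) <- paste0("factor", seq_len(k))
  rownames(f) <- colnames(normalized)
  f
}
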