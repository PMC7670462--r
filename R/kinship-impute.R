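#' Frequency-standardized (Balding-Nichols style) kinship matrix
#'
#' Builds the accession-by-accession genetic similarity matrix used to
#' control relatedness and population structure in the mixed-model scan:
#' per-site dosages are centred by twice the allele frequency and scaled by
#' the binomial SD `sqrt(2 p (1-p))`, missing dosages are mean-filled, and
#' the standardized identity is averaged over sites.  The result is
#' symmetric and positive semi-definite; monomorphic sites carry no
#' information and are dropped.
#'
#' @param dosages sites x accessions matrix of A-allele dosages (0/1/2,
#'   NA allowed).
#' @return accessions x accessions kinship matrix.
#' @export
compute_kinship <- function(dosages) {
  if (!all(dosages %in% c(0, 1, 2, NA)))
    stop("dosages must be 0, 1, 2 or NA")
  p <- rowMeans(dosages, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic site: kinship undefined")
  d <- dosages[poly, , drop = FALSE]
  p <- p[poly]
  mu <- 2 * p
  for (i in seq_len(nrow(d)))   # mean-fill missing per site
    d[i, is.na(d[i, ])] <- mu[i]
  z <- (d - mu) / sqrt(2 * p * (1 - p))
  K <- crossprod(z) / nrow(z)
  dimnames(K) <- list(colnames(dosages), colnames(dosages))
  K
}

#' KNN imputation parameters
#'
#' @param w window size in sites around the imputed site.
#' @param k number of nearest neighbour accessions.
#' @param p distance weighting exponent (negative: closer neighbours weigh
#'   more).
#' @param r minimum weighted neighbour concordance required to fill.
#' @return validated parameter list.
#' @export
imputation_params <- function(w = 80, k = 3, p = -7, r = 0.8) {
  if (!(w >= k && k >= 1)) stop("need w >= k >= 1")
  if (!(r > 0 && r <= 1)) stop("r must lie in (0, 1]")
  list(w = as.integer(w), k = as.integer(k), p = p, r = r)
}

#' K-nearest-neighbour genotype imputation
#'
#' Fills each missing dosage from the `k` accessions nearest to the focal
#' accession over a window of `w` surrounding sites (allele-sharing
#' distance over mutually called sites; neighbours weighted by
#' `distance^p`).  The fill is applied only when the weighted vote for the
#' winning dosage class reaches the concordance threshold `r`; otherwise
#' the call stays missing.  Non-missing entries are never modified.  Sites
#' missing in every accession are left missing.
#'
#' @param dosages sites x accessions dosage matrix (rows in genome order).
#' @param params an [imputation_params()] list.
#' @return list with `dosages` (imputed matrix) and `fill_rate` (fraction
#'   of missing cells filled).
#' @export
knn_impute <- function(dosages, params = imputation_params()) {
  n_sites <- nrow(dosages); n_acc <- ncol(dosages)
  half <- params$w %/% 2
  filled <- 0L; missing_total <- sum(is.na(dosages))
  out <- dosages
  miss_sites <- which(rowSums(is.na(dosages)) > 0)
  for (s in miss_sites) {
    lo <- max(1L, s - half); hi <- min(n_sites, s + half)
    W <- dosages[lo:hi, , drop = FALSE]
    have <- which(!is.na(dosages[s, ]))
    if (!length(have)) next
    for (j in which(is.na(dosages[s, ]))) {
      dif <- abs(W[, have, drop = FALSE] - W[, j])
      shared <- colSums(!is.na(dif))
      dist <- colSums(dif, na.rm = TRUE) / (2 * shared)
      ok <- shared >= 3
      if (!any(ok)) next
      cand <- have[ok]; dist <- dist[ok]
      k <- min(params$k, length(cand))
      sel <- order(dist)[seq_len(k)]
      wts <- (dist[sel] + 1e-6)^params$p
      votes <- tapply(wts, dosages[s, cand[sel]], sum)
      conc <- max(votes) / sum(votes)
      if (conc >= params$r) {
        out[s, j] <- as.integer(names(votes)[which.max(votes)])
        filled <- filled + 1L
      }
    }
  }
  list(dosages = out,
       fill_rate = if (missing_total) filled / missing_total else 1)
}

#' Masking experiment for imputation accuracy
#'
#' Randomly masks a fraction of the called cells, imputes them back, and
#' reports fill rate and accuracy against the masked truth — the standard
#' way of choosing the imputation parameter combination.
#'
#' @param dosages complete (or mostly complete) dosage matrix.
#' @param mask_frac fraction of called cells to mask.
#' @param params an [imputation_params()] list.
#' @param seed RNG seed for the mask.
#' @return list with `accuracy` (filled cells equal to truth), `fill_rate`,
#'   `n_masked`.
#' @export
evaluate_imputation <- function(dosages, mask_frac = 0.10,
                                params = imputation_params(), seed = 1) {
  set.seed(seed)
  called <- which(!is.na(dosages))
  n_mask <- max(1L, round(mask_frac * length(called)))
  mask <- sample(called, n_mask)
  masked <- dosages
  masked[mask] <- NA_integer_
  imp <- knn_impute(masked, params)
  got <- imp$dosages[mask]
  ok <- !is.na(got)
  list(accuracy = if (any(ok)) mean(got[ok] == dosages[mask][ok]) else NA,
       fill_rate = mean(ok), n_masked = n_mask)
}
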