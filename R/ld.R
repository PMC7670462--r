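#' Background linkage disequilibrium level and distance
#'
#' Computes pairwise r-squared between dosage vectors of same-chromosome
#' site pairs within `max_dist`, bins the values by physical distance, and
#' locates the decay plateau: the background LD level is the mean r-squared
#' over the bins where the smoothed decay curve's slope magnitude has
#' fallen below 1% of its initial value, and the background distance is the
#' first distance at which the smoothed curve reaches that level.  When no
#' plateau exists within `max_dist`, the r-squared of the last bin is
#' returned with a warning.
#'
#' @param dosages sites x accessions dosage matrix.
#' @param sites data.frame with `chrom` and `pos` aligned to the rows.
#' @param max_dist maximum pair distance in bp.
#' @param bin_width distance bin width in bp.
#' @param smooth_k running-mean window (bins) for the decay curve.
#' @return list with `r2_bg`, `dist_bg`, and the binned `decay` table
#'   (`dist`, `r2`, `n_pairs`).
#' @export
ld_background <- function(dosages, sites, max_dist = 10e6,
                          bin_width = 50e3, smooth_k = 5) {
  if (nrow(dosages) < 2) stop("need at least 2 sites")
  keep <- which(apply(dosages, 1, stats::sd, na.rm = TRUE) > 0)
  if (length(keep) < 2) stop("need at least 2 polymorphic sites")
  d <- dosages[keep, , drop = FALSE]
  st <- sites[keep, , drop = FALSE]
  r2 <- stats::cor(t(d), use = "pairwise.complete.obs")^2
  n <- nrow(d)
  same_chrom <- outer(st$chrom, st$chrom, "==")
  dist <- abs(outer(st$pos, st$pos, "-"))
  ut <- upper.tri(r2)
  sel <- ut & same_chrom & dist <= max_dist
  pr2 <- r2[sel]; pd <- dist[sel]
  ok <- !is.na(pr2)
  pr2 <- pr2[ok]; pd <- pd[ok]
  if (!length(pr2)) stop("no usable site pair within max_dist")

  bins <- floor(pd / bin_width)
  tab <- data.frame(
    dist = (sort(unique(bins)) + 0.5) * bin_width,
    r2 = as.numeric(tapply(pr2, bins, mean)),
    n_pairs = as.integer(table(bins)))

  if (nrow(tab) < 3) {
    warning("too few distance bins for a plateau; returning last-bin r2")
    return(list(r2_bg = tab$r2[nrow(tab)], dist_bg = max_dist,
                decay = tab))
  }
  sm <- running_mean(tab$r2, smooth_k)
  if ((max(sm) - min(sm)) < 0.5 * max(mean(sm), 1e-12)) {
    # no appreciable decay: the whole curve is background
    return(list(r2_bg = mean(tab$r2), dist_bg = tab$dist[1], decay = tab))
  }
  slope <- diff(sm) / diff(tab$dist)
  s0 <- slope[1]
  flat <- if (abs(s0) < 1e-12) rep(TRUE, length(slope)) else
    abs(slope) < 0.01 * abs(s0)
  start <- which(flat)
  if (!length(start)) {
    warning("no LD plateau within max_dist; returning last-bin r2")
    return(list(r2_bg = tab$r2[nrow(tab)], dist_bg = max_dist,
                decay = tab))
  }
  i0 <- start[1] + 1L
  r2_bg <- mean(tab$r2[i0:nrow(tab)])
  reach <- which(sm <= r2_bg + 1e-9)
  dist_bg <- if (length(reach)) tab$dist[reach[1]] else max_dist
  list(r2_bg = r2_bg, dist_bg = dist_bg, decay = tab)
}

running_mean <- function(x, k) {
  n <- length(x)
  half <- k %/% 2
  vapply(seq_len(n), function(i)
    mean(x[max(1, i - half):min(n, i + half)]), numeric(1))
}

#' Pairwise r-squared between two dosage vectors
#'
#' @param g1,g2 dosage vectors.
#' @return squared Pearson correlation (0 for monomorphic input).
#' @export
pair_r2 <- function(g1, g2) {
  if (stats::sd(g1, na.rm = TRUE) == 0 || stats::sd(g2, na.rm = TRUE) == 0)
    return(0)
  stats::cor(g1, g2, use = "pairwise.complete.obs")^2
}
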