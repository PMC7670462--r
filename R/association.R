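#' Bonferroni significance threshold
#'
#' @param alpha family-wise error target (> 0).
#' @param m number of tests (>= 1).
#' @return list with `threshold = alpha / m` and `neg_log10` its -log10.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (alpha <= 0) stop("alpha must be > 0")
  if (m < 1) stop("m must be >= 1")
  thr <- alpha / m
  list(threshold = thr, neg_log10 = -log10(thr))
}

#' Filter SV sites for association mapping
#'
#' Keeps biallelic sites with minor allele frequency at least `maf` and
#' missing-call rate at most `max_missing`.
#'
#' @param dosages sites x accessions dosage matrix.
#' @param maf minimum minor allele frequency.
#' @param max_missing maximum missing fraction.
#' @return logical vector of retained rows.
#' @export
filter_sv_sites <- function(dosages, maf = 0.01, max_missing = 0.40) {
  p <- rowMeans(dosages, na.rm = TRUE) / 2
  miss <- rowMeans(is.na(dosages))
  !is.na(p) & pmin(p, 1 - p) >= maf & miss <= max_missing
}

# Restricted maximum likelihood for the variance ratio delta = sigma_e^2 /
# sigma_g^2 on the eigenbasis of the kinship matrix (the one-time
# spectral-decomposition trick): yt, Xt are U'y and U'X, vals the kinship
# eigenvalues.
reml_delta <- function(yt, Xt, vals) {
  n <- length(yt); q <- ncol(Xt)
  ldet_xx <- determinant(crossprod(Xt), logarithm = TRUE)$modulus
  nll <- function(log_delta) {
    d <- vals + exp(log_delta)
    w <- 1 / d
    XtWX <- crossprod(Xt, Xt * w)
    XtWy <- crossprod(Xt, yt * w)
    bh <- solve(XtWX, XtWy)
    rss <- sum(yt * w * yt) - sum(XtWy * bh)
    sigma2 <- rss / (n - q)
    0.5 * ((n - q) * log(sigma2) + sum(log(d)) +
             determinant(XtWX, logarithm = TRUE)$modulus - ldet_xx)
  }
  grid <- seq(-8, 8, length.out = 33)
  vals_nll <- vapply(grid, nll, numeric(1))
  i <- which.min(vals_nll)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(nll, c(lo, hi))
  exp(opt$minimum)
}

#' EMMAX-style mixed-model association scan for one trait
#'
#' Two-step approximation to the linear mixed model
#' `y = X b + g beta + u + e`, `u ~ N(0, sigma_g^2 K)`: the variance ratio
#' is estimated once per trait by restricted maximum likelihood under the
#' null (no SV term), then every SV is tested by generalized least squares
#' with that fixed covariance.  With an identity kinship the scan reduces
#' exactly to ordinary linear regression.
#'
#' @param y trait vector (one gene's normalized expression), one value per
#'   accession.
#' @param dosages sites x accessions dosage matrix (pre-imputed; residual
#'   missing dosages are mean-filled for testing).
#' @param covariates accessions x c covariate matrix (hidden factors, ...);
#'   an intercept is always added.
#' @param kinship accessions x accessions kinship (default identity).
#' @param maf,max_missing site filters applied before testing.
#' @return data.frame with `sv_id`, `beta`, `se`, `p` for each tested SV;
#'   zero-variance SVs are skipped.
#' @export
association_scan <- function(y, dosages, covariates = NULL, kinship = NULL,
                             maf = 0.01, max_missing = 0.40) {
  pre <- precompute_mixed_model(dosages, covariates, kinship,
                                maf, max_missing)
  scan_one_trait(y, pre)
}

# Shared pre-computation: site filtering, eigen-decomposition of K, and
# rotation of covariates and dosages, reused across traits.
precompute_mixed_model <- function(dosages, covariates = NULL,
                                   kinship = NULL, maf = 0.01,
                                   max_missing = 0.40) {
  keep <- filter_sv_sites(dosages, maf, max_missing)
  d <- dosages[keep, , drop = FALSE]
  n <- ncol(d)
  # mean-fill residual missing dosages
  if (anyNA(d)) {
    mu <- rowMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 1]]
  }
  X <- cbind(intercept = rep(1, n), covariates)
  if (is.null(kinship)) {
    U <- diag(n); vals <- rep(1, n)
  } else {
    ed <- eigen(kinship, symmetric = TRUE)
    U <- ed$vectors
    vals <- pmax(ed$values, 0)
  }
  list(U = U, vals = vals,
       Xt = crossprod(U, X),
       Gt = crossprod(U, t(d)),
       sv_id = rownames(d), n = n, q = ncol(X))
}

scan_one_trait <- function(y, pre) {
  yt <- as.numeric(crossprod(pre$U, y))
  delta <- reml_delta(yt, pre$Xt, pre$vals)
  sw <- 1 / sqrt(pre$vals + delta)
  ys <- yt * sw
  Xs <- pre$Xt * sw
  Gs <- pre$Gt * sw
  qr_x <- qr(Xs)
  yr <- qr.resid(qr_x, ys)
  Gr <- qr.resid(qr_x, Gs)
  gg <- colSums(Gr^2)
  gy <- as.numeric(crossprod(Gr, yr))
  ok <- gg > 1e-10
  beta <- gy[ok] / gg[ok]
  df <- pre$n - pre$q - 1
  rss <- sum(yr^2) - beta^2 * gg[ok]
  rss <- pmax(rss, 0)
  se <- sqrt(rss / df / gg[ok])
  tstat <- ifelse(se > 0, beta / se, Inf)
  p <- 2 * stats::pt(-abs(tstat), df)
  data.frame(sv_id = pre$sv_id[ok], beta = beta, se = se,
             p = pmin(pmax(p, .Machine$double.xmin), 1),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Genome-wide eQTL scan over all genes
#'
#' Runs [association_scan()] for every gene of an expression matrix against
#' the same dosage matrix, kinship and covariates, sharing the one-time
#' spectral decomposition across genes.
#'
#' @param expr genes x accessions matrix of normalized expression.
#' @param dosages,covariates,kinship,maf,max_missing as in
#'   [association_scan()].
#' @param p_keep drop results with p above this value to bound memory
#'   (default keeps everything).
#' @return data.frame with `gene_id`, `sv_id`, `beta`, `se`, `p`.
#' @export
eqtl_scan <- function(expr, dosages, covariates = NULL, kinship = NULL,
                      maf = 0.01, max_missing = 0.40, p_keep = 1) {
  pre <- precompute_mixed_model(dosages, covariates, kinship,
                                maf, max_missing)
  res <- lapply(rownames(expr), function(g) {
    r <- scan_one_trait(expr[g, ], pre)
    r <- r[r$p <= p_keep, , drop = FALSE]
    if (nrow(r)) cbind(gene_id = g, r, stringsAsFactors = FALSE) else NULL
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(gene_id = character(), sv_id = character(),
                      beta = numeric(), se = numeric(), p = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
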