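test_that("Bonferroni threshold is exactly alpha over m", {
  for (alpha in c(0.05, 1)) for (m in c(1, 37, 71684)) {
    thr <- bonferroni_threshold(alpha, m)
    expect_identical(thr$threshold * m, alpha)
    expect_equal(thr$neg_log10, -log10(alpha / m))
  }
  expect_equal(bonferroni_threshold(0.05, 1)$threshold, 0.05)
  expect_error(bonferroni_threshold(0, 10), "alpha")
  expect_error(bonferroni_threshold(0.05, 0), "m must")
})

test_that("site filtering enforces MAF and missingness bounds", {
  d <- rbind(rep(0L, 10),                    # monomorphic
             c(rep(2L, 5), rep(0L, 5)),      # fine
             c(1L, rep(0L, 9)),              # MAF 0.05
             c(rep(NA, 5), rep(2L, 3), 0L, 0L))  # 50% missing
  keep <- filter_sv_sites(d, maf = 0.10, max_missing = 0.40)
  expect_equal(keep, c(FALSE, TRUE, FALSE, FALSE))
})

test_that("identity kinship reduces the mixed model to ordinary regression", {
  set.seed(6)
  n <- 80
  d <- matrix(rbinom(30 * n, 2, 0.4), 30, n,
              dimnames = list(paste0("s", 1:30), paste0("a", 1:n)))
  y <- 0.8 * d[5, ] + rnorm(n)
  res <- association_scan(y, d, kinship = diag(n))
  for (s in c("s5", "s12", "s20")) {
    ols <- summary(lm(y ~ d[s, ]))$coefficients[2, ]
    row <- res[res$sv_id == s, ]
    expect_equal(row$beta, unname(ols[1]), tolerance = 1e-6)
    expect_equal(row$p, unname(ols[4]), tolerance = 1e-3 * unname(ols[4]) + 1e-12)
  }
})

test_that("zero-variance genotypes are skipped after filtering", {
  set.seed(7)
  n <- 40
  d <- matrix(rbinom(10 * n, 2, 0.5), 10, n,
              dimnames = list(paste0("s", 1:10), NULL))
  d[3, ] <- 1L   # constant but MAF 0.5 under dosage coding
  y <- rnorm(n)
  res <- association_scan(y, d, maf = 0)
  expect_false("s3" %in% res$sv_id)
})

test_that("the mixed model keeps power for a strong planted effect", {
  # planted effect under population structure: lead p clears the
  # study-scale Bonferroni threshold in most replicates
  hits <- sapply(1:5, function(s) {
    cfg <- eqtl_scenario_config(seed = 100 + s, n_cis = 1, cis_beta = 1.5)
    cfg$n_genes <- 2L
    cfg$hotspot <- NULL
    pair <- simulate_genome_pair(cfg)
    gm <- simulate_population_genotypes(pair$truth, cfg)
    es <- simulate_expression(gm, cfg)
    norm <- normalize_expression(fpkm = es$values)
    acc <- colnames(norm$normalized)
    dos <- knn_impute(gm$dosage[, acc])$dosages
    kin <- compute_kinship(dos)
    res <- association_scan(norm$normalized["gene0001", ], dos,
                            kinship = kin)
    min(res$p) < bonferroni_threshold(0.05, 71684)$threshold
  })
  expect_gte(mean(hits), 0.8)
})

test_that("REML delta recovers the simulated variance ratio regime", {
  set.seed(9)
  n <- 100
  z <- matrix(rnorm(n * 200), 200, n)
  K <- crossprod(z) / 200
  L <- chol(K + 1e-8 * diag(n))
  u <- drop(crossprod(L, rnorm(n)))       # genetic effect, var 1
  y <- u + rnorm(n, 0, sqrt(2))           # delta = 2
  pre <- svdomest:::precompute_mixed_model(
    matrix(rbinom(5 * n, 2, 0.5), 5, n), NULL, K, maf = 0)
  yt <- as.numeric(crossprod(pre$U, y))
  delta <- svdomest:::reml_delta(yt, pre$Xt, pre$vals)
  expect_gt(delta, 0.5); expect_lt(delta, 8)
})
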