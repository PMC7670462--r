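#' Simulate expression with planted cis effects and a trans hotspot
#'
#' Builds a gene set with coordinates on genome A and an expression matrix
#' whose value for gene g in accession j is
#' `baseline + sum(beta * A-allele dose) + trans effects + N(0, noise_sd)`.
#' Genes named in `config$cis_effects` are placed so their causal SV lies
#' within the 50-kb cis window of the TSS; all other genes are placed away
#' from any planted effect.  A `config$hotspot` places one regulator gene
#' next to its own cis SV and adds `beta * (regulator expression, centred)`
#' to each target gene, so targets acquire trans associations at the
#' regulator locus.  True dosages (not missing-injected calls) drive the
#' signal.
#'
#' @param gm [genotype_matrix()] from [simulate_population_genotypes()].
#' @param config a [sim_config()] object.
#' @return list of class `"expression_set"`: `values` (genes x accessions),
#'   `genes` (gene_id, chrom, tss, tes, strand), `truth_effects`
#'   (gene, sv, beta, type).
#' @export
simulate_expression <- function(gm, config) {
  if (ncol(gm$dosage) < 20) stop("need at least 20 accessions")
  set.seed(stage_seed(config, "expression"))
  dos <- if (!is.null(gm$truth_dosage)) gm$truth_dosage else gm$dosage
  sites <- gm$sites
  n_genes <- config$n_genes
  n_acc <- ncol(dos)
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))

  chk_gene <- function(g) {
    if (any(g < 1 | g > n_genes)) stop("effect references unknown gene")
  }
  chk_sv <- function(s) {
    if (any(s < 1 | s > nrow(sites))) stop("effect references unknown SV")
  }

  # gene placement: null genes uniform, effect genes near their SV
  chroms <- unique(sites$chrom)
  max_pos <- vapply(chroms, function(ch)
    max(sites$pos[sites$chrom == ch]) + 5e4, numeric(1))
  gchrom <- sample(chroms, n_genes, replace = TRUE)
  tss <- vapply(seq_len(n_genes), function(i)
    stats::runif(1, 0, max_pos[[gchrom[i]]]), numeric(1))

  place_near <- function(gene, sv) {
    gchrom[gene] <<- sites$chrom[sv]
    tss[gene] <<- max(0, sites$pos[sv] +
                        round(stats::runif(1, -2e4, 2e4)))
  }

  eff <- data.frame(gene = integer(), sv = integer(), beta = numeric(),
                    type = character(), stringsAsFactors = FALSE)
  values <- matrix(stats::rnorm(n_genes * n_acc, 0, config$noise_sd),
                   n_genes, n_acc,
                   dimnames = list(gene_ids, colnames(dos))) +
    config$expr_baseline

  if (!is.null(config$cis_effects) && nrow(config$cis_effects)) {
    ce <- config$cis_effects
    chk_gene(ce$gene); chk_sv(ce$sv)
    for (i in seq_len(nrow(ce))) {
      place_near(ce$gene[i], ce$sv[i])
      values[ce$gene[i], ] <- values[ce$gene[i], ] +
        ce$beta[i] * dos[ce$sv[i], ]
    }
    eff <- rbind(eff, data.frame(gene = ce$gene, sv = ce$sv,
                                 beta = ce$beta, type = "cis"))
  }

  hs <- config$hotspot
  if (!is.null(hs)) {
    chk_gene(c(hs$regulator_gene, hs$targets)); chk_sv(hs$regulator_sv)
    place_near(hs$regulator_gene, hs$regulator_sv)
    values[hs$regulator_gene, ] <- values[hs$regulator_gene, ] +
      hs$regulator_beta * dos[hs$regulator_sv, ]
    reg <- values[hs$regulator_gene, ]
    reg_c <- reg - mean(reg)
    reg_chrom <- sites$chrom[hs$regulator_sv]
    reg_pos <- sites$pos[hs$regulator_sv]
    # targets live far from the regulator locus (trans by construction);
    # the required distance adapts to short toy chromosomes
    trans_dist <- min(2e6, max(1e5, 0.2 * max(unlist(max_pos))))
    for (g in hs$targets) {
      tries <- 0L
      while (gchrom[g] == reg_chrom &&
               abs(tss[g] - reg_pos) < trans_dist && tries < 100L) {
        gchrom[g] <- sample(chroms, 1L)
        tss[g] <- stats::runif(1, 0, max_pos[[gchrom[g]]])
        tries <- tries + 1L
      }
      values[g, ] <- values[g, ] + hs$beta * reg_c
    }
    eff <- rbind(eff,
                 data.frame(gene = hs$regulator_gene, sv = hs$regulator_sv,
                            beta = hs$regulator_beta, type = "cis"),
                 data.frame(gene = hs$targets, sv = hs$regulator_sv,
                            beta = hs$beta, type = "trans"))
  }

  genes <- data.frame(gene_id = gene_ids, chrom = gchrom,
                      tss = round(tss), tes = round(tss) + 2000,
                      strand = "+", stringsAsFactors = FALSE)
  structure(list(values = values, genes = genes, truth_effects = eff),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat("Expression set: ", nrow(x$values), " genes x ", ncol(x$values),
      " accessions; ", nrow(x$truth_effects), " planted effect(s)\n",
      sep = "")
  invisible(x)
}
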