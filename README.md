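# svdomest

Structural variants (SVs) — insertions, deletions and inversions of 10 bp
and up — are major drivers of crop domestication phenotypes.  `svdomest`
implements, as a tested and reusable R pipeline, an SV-centric population
analysis for a wild-vs-cultivated species pair with two reference genome
assemblies (the motivating system is wild *Solanum pimpinellifolium*
versus cultivated tomato): it validates and merges candidate SVs called
between the two assemblies, genotypes the merged reference SV set across
a population from split-read and read-depth evidence, scans
allele-frequency changes across domestication stages, computes windowed
diversity and differentiation, detects wild-donor introgressions, and
maps expression QTLs with a linear mixed model, including LD-clustered
eQTL blocks, cis/trans classification, trans-eQTL hotspots and
master-regulator ranking.  A synthetic-data module generates every input
with machine-readable truth, so the whole pipeline runs end to end with
no external data.

It is aimed at plant population genomicists who want the analysis logic
of such a study as composable, testable functions rather than a chain of
external tools.

## The methods in brief

* **SV validation** — candidate SVs near assembly gaps (< 50 bp) are
  discarded; inversions require > 90% split reads at every breakpoint or
  support from both read-mapping callers; indels require qualifying flank
  anchors on the other genome (alignment > 50 bp, identity > 90%,
  e-value < 1e-10) with geometry consistent with the SV (insertions:
  flank distance within 20% of the read-based size estimate; deletions:
  gap/overlap < 3 bp); fuzzy repeat-length records are converted to
  precise indels; call sets are merged at > 50% reciprocal overlap.
* **Genotyping** — per accession and SV, the allele lacking a segment is
  supported by ≥ 3 split reads at a breakpoint or by the depth rule
  (< 50% of the segment covered at 2x while > 50% of an equal-length
  flank is covered); the segment-carrying allele by ≥ 3 split reads at
  the other genome's junction or ≥ 3 spanning reads.  Both alleles
  supported → heterozygote; neither → missing.  Accessions with < 40% of
  SVs genotyped are dropped.
* **Selection scan** — per SV and stage transition (wild → early
  domesticate → heirloom → modern), a two-tailed Fisher exact test on
  the 2x2 allele-count table, Bonferroni-corrected; corrected *P* < 0.001
  flags selection.
* **Diversity / differentiation** — nucleotide diversity
  `2p(1-p)·n/(n-1)` and Weir–Cockerham F_ST (ratio of averages) in
  1000-kb windows with 250-kb steps.
* **Introgression** — per cultivated accession and SV, the ratio of
  own-group genotype sharing to wild-group sharing; windows with mean
  ratio ≤ 0.9 and ≥ 2 SVs are introgressions.
* **eQTL mapping** — FPKM normalization, median-zero and PCA-outlier
  (2.5 SD) filters, per-gene normal-quantile transform, KNN genotype
  imputation (w = 80, k = 3, p = −7, r = 0.8), Balding–Nichols-style
  kinship, hidden expression factors, then an EMMAX-style two-step mixed
  model (per-gene REML variance components, per-SV generalized least
  squares).  Significant SVs chain into blocks when adjacent r² exceeds
  the background LD level within the background LD distance; blocks need
  ≥ 3 SVs; a block is *cis* when its lead SV lies within 50 kb of the
  gene's transcription start or stop site.  Trans lead SVs are scanned
  for 50-kb hotspot windows (Poisson clustering test, BH-adjusted
  *P* < 0.05), and each hotspot's master regulator is ranked by
  iterative-group-analysis enrichment of target genes among the genes
  best correlated with each candidate.

## Worked example

```r
library(svdomest)

cfg <- sim_config(seed = 7)            # toy 2-chromosome scenario
out <- run_pipeline(cfg)

out$truth
#> SV truth set: 22 SVs, 178 SNPs
#>  deletion insertion inversion
#>        12         8         2

nrow(out$reference_svs)                # validated + merged reference set
#> [1] 22

out$genotypes
#> SV genotype matrix: 22 SVs x 300 accessions
#>   groups: SP=50, SLC=100, heirloom=100, modern=50
#>   missing calls: 2.2%

head(out$composition[out$composition$group == "SP", c("accession", "f_a_hom", "f_b_hom")])
# per-accession genotype composition: wild accessions are dominated by
# homozygous wild (A) alleles, cultivated accessions by cultivar (B) alleles
```

On the larger canned eQTL scenario (150 accessions, 2,000 SVs, 300
genes, 20 planted cis effects, one trans hotspot):

```r
res <- evaluate_eqtl_recovery(seed = 1)
res$cis_recovery     # fraction of planted cis effects recovered as cis
#> [1] 0.85           # blocks containing the causal SV
res$regulator_top    # planted master regulator ranked first in its hotspot
#> [1] TRUE
```

`cis_recovery` is the fraction of the 20 planted cis effects that end up
in a cis-classified eQTL block containing the causal SV;
`regulator_top` reports whether the hotspot scan found the planted
regulator gene and ranked it first among the hotspot's candidates.

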