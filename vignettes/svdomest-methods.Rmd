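---
title: "Methods: SV population genomics and eQTL mapping with svdomest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SV population genomics and eQTL mapping with svdomest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`svdomest` re-implements, as composable R functions, an SV-centric
population analysis for a wild/cultivated crop pair with two reference
assemblies: reference-SV validation and merging, population genotyping
from read evidence, selection and introgression scans across
domestication stages, and mixed-model eQTL mapping.  This vignette
documents the models, the tunable parameters, the synthetic-data
generator that stands in for real sequencing data, and the numerical
and design choices made where the methods left room.

## Coordinates and allele labels

All internal coordinates are 0-based half-open intervals; emitted
SAM/VCF/GFF3/BED files follow their own standards (SAM/VCF/GFF3
1-based, BED 0-based half-open).  Symbolic-ALT SV VCF records anchor
`POS` one base before the event, so a deletion `[start, end)` is
written `POS = start`, `END = end`, `SVLEN = -(end - start)`.
Throughout, allele "A" is the wild-reference state and allele "B" the
cultivar-reference state; genotype matrices store the A-allele dosage
(2 = homozygous wild, 1 = heterozygous, 0 = homozygous cultivar,
NA = missing), and the flat TSV export codes the same `0/1/2/NA`.

## The synthetic-data generator

The generator's job is to emulate the statistical structure the
analysis assumes, with known truth, at desk scale.

**Genome pair.** `simulate_genome_pair()` draws a random genome A and
derives genome B by applying planted deletions, insertions, inversions
(sizes uniform within `sv_size_range`, floor 10 bp) and SNPs.  SVs are
placed one per chromosome slot with generous margins, so no two SVs
overlap and their local read-evidence windows are disjoint.  The truth
set records both-genome breakpoints for every variant.

**Population genotypes.** `simulate_population_genotypes()` uses an
archetype-mosaic haplotype model: each haplotype is a mosaic of the two
reference archetypes (all-A vs all-B), with segment lengths exponential
with mean `recomb_mean_segment` and the per-segment archetype drawn
with the group's A frequency (adjusted for flip noise).  A small
per-locus flip probability (`founder_flip`, jittered per locus by
`drift_sd`) keeps neighbouring loci from being perfect copies and
injects per-locus drift.  An `inbreeding` parameter (default 0.95 —
tomato is strongly autogamous, and published stage-composition box
plots show only a few percent heterozygous calls, far below
Hardy-Weinberg) is the probability that an accession's two haplotypes
are identical copies.  This model makes three things emerge at once:
strong local LD decaying over the segment scale, structure-induced
background LD when stages are pooled, and realistic genotype
composition per stage.  Default per-group A frequencies (SP 0.60,
SLC 0.16, heirloom 0.05, modern 0.065) follow the published
domestication trajectory, including the slight wild-allele recovery in
modern lines.  Selection is modeled as forced per-group target
frequencies at chosen loci (the analysis consumes frequencies, not
genealogies, so a completed sweep is just a frequency displacement);
this breaks local LD at the swept locus only.  Planted introgressions
copy a wild donor's genotypes into a fraction of focal-group accessions
over a block; donors are drawn from the most wild-allele-rich SP
accessions because introgressed material carries wild-specific alleles
— a donor segment identical to the cultivar haplotype would be
undetectable in principle.

**Read evidence.** `simulate_read_evidence()` emits idealized
alignments on both reference coordinate systems: Poisson coverage,
uniform read starts along the accession's local haplotypes, full-length
matches where haplotype and reference agree, clipped/SA-tagged split
records where a read crosses a junction the reference lacks, and
omitted (unmapped) records for reads wholly inside a segment the
reference lacks.  Two idealizations matter: all junction-crossing reads
are represented as clipped/split records even for SVs shorter than a
read (a real aligner would emit CIGAR I/D operations there), and there
are no base-call errors or mismapped reads.  Passing genotype-recovery
tests therefore demonstrate the decision rules, not robustness to
alignment noise.

**Expression.** `simulate_expression()` places genes on genome A (cis
genes within the 50-kb window of their causal SV, hotspot targets far
from the regulator locus), and builds expression as baseline + per-dose
cis effects + regulator-mediated trans effects + Gaussian noise.
Values are on an abundance-like continuous scale; the normalization
step treats them exactly like FPKM.

**Determinism.** Every simulator derives its RNG stream from the one
configured seed (with fixed per-stage offsets, and per-SV/accession
salts for read evidence), so identical configurations give
byte-identical outputs across all operations.

## Reference-SV validation

`filter_gap_proximity()` removes SVs overlapping or closer than 50 bp
to an assembly gap on either genome.  `validate_inversion()` accepts an
inversion when more than 90% of reads spanning every breakpoint are
split reads, or when both read-mapping callers report it; a breakpoint
with zero spanning reads fails the split criterion (insufficient
evidence) rather than erroring.  `validate_indel_flanks()` requires a
qualifying hit for both 5-kb flanks (length > 50 bp, identity > 90%,
e-value < 1e-10) inside the expected query region — decided here as
within `2 x size estimate + 10 kb` of the projected position, since the
method names the idea but no tolerance — and checks hit geometry:
insertions within 20% of the read-based size estimate, deletions with
less than 3 bp of gap or overlap.  `normalize_repeat_svs()` replaces
fuzzy repeat/tandem expansion-contraction records by the precise
read-mapping indels they contain, dropping records with no precise
match.  `merge_sv_sets()` combines same-type records at > 50%
reciprocal overlap, keeping set-1 coordinates and the union of sources;
insertions, whose genome-A interval is degenerate, pair by breakpoint
distance (<= 100 bp) and size ratio (> 0.5).  Ties are resolved by the
larger reciprocal overlap, then leftmost start, making the merge
deterministic; merging a set with itself is idempotent.  How
multi-allelic or nested SVs were resolved is not described in the
source method; they are left unmerged rather than guessed.

## Population genotyping

`dedup_read_pairs()` collapses read pairs identical over the first
90 bp (100-bp reads) or 100 bp (150-bp reads) of both mates.
`collect_evidence()` summarizes, per SV and accession, clip-boundary
split reads within +-10 bp of each breakpoint (the method states no
tolerance; 10 bp absorbs alignment jitter), essentially unclipped reads
spanning each breakpoint by >= 20 bp, and per-base depth over the
deleted/inserted segment and its equal-length flanks on the carrier
genome.  `call_genotype()` is a pure function of that summary:
inversions accept only split-read support (>= 3 at every breakpoint per
allele orientation); for indels the segment-absent allele is supported
by >= 3 split reads at a breakpoint or by the depth rule (< 50% of the
segment covered at 2x while > 50% of a flank is covered) — the depth
rule serving as the fallback when split support is thin — and the
segment-present allele by >= 3 split reads at the other genome's
junction or >= 3 spanning reads with the segment covered.  Both alleles
supported gives a heterozygote, one the homozygote, neither a missing
call.  Insertion genotyping mirrors deletion logic with the genomes
swapped (the inserted segment is a "deleted region" of genome A seen
from genome B).  `build_genotype_matrix()` never alters calls; it only
drops accessions genotyped at fewer than 40% of SVs (exactly 40% is
retained).  `concordance()` compares two call matrices over shared
non-missing cells, as when validating short-read calls against an
independent long-read call set.

## Selection, diversity, introgression

`group_allele_frequencies()` counts alleles (2 per homozygote, 1 each
per heterozygote) over non-missing calls.  `fisher_selection_scan()`
tests each SV's 2x2 allele-count table between two stages with the
two-tailed Fisher exact test (the standard convention: sum of
probabilities of tables, at fixed margins, whose point probability does
not exceed the observed one), Bonferroni-corrects over the number of
SVs tested in that pair (the denominator is a parameter; whether the
original correction used the per-pair count or the full SV catalogue is
not stated), and flags corrected *P* < 0.001.  Heterozygotes contribute
one allele of each type: the scan is an allele-count test, matching the
frequencies being compared.

`windowed_diversity_fst()` computes per-site diversity
`2p(1-p)·n/(n-1)` summed over a window and divided by window length,
and two-population Weir-Cockerham F_ST aggregated per window as a ratio
of averages — the conventions of the standard VCF tools, since the
source names the tool rather than a formula.  Negative F_ST estimates
are reported unclipped.  Windows are 1000-kb with 250-kb steps;
trailing windows truncate at the chromosome end.  The site table may
hold SVs, SNPs, or both — the operation accepts any biallelic sites.

`introgression_scan()` computes, per focal accession and SV, the ratio
of own-group genotype sharing (exact state match, the accession itself
excluded, missing calls excluded) to wild-donor-group sharing; sites
the donor group never shows are skipped for that accession.  Windows
(1000-kb/250-kb) with mean ratio <= 0.9 over >= 2 SVs are emitted.

## eQTL mapping

`normalize_expression()`: FPKM = `count·1e9/(length·library)`, genes
with median zero dropped, accessions beyond 2.5 SD on any of the first
three principal components dropped, then a per-gene rank-to-normal
transform (mid-ranks on ties, classical normal-scores offsets; no
random tie-jitter, for determinism).

`derive_hidden_factors()` returns leading principal components of the
normalized matrix as covariates, the proxy used here for hidden
expression factors (a variational factor model would fill the same
covariate role).  One guard matters at simulation scale: a genetically
driven co-expression module — exactly the signal a trans-hotspot scan
looks for — concentrates its loadings on its member genes, while
technical confounders load broadly.  With 300 simulated genes, a
15-target hotspot dominates a leading component and would be regressed
away; `drop_concentrated = TRUE` (used by the pipeline driver) skips
components whose squared loadings concentrate more than 50% on the top
5% of genes.  At transcriptome scale (tens of thousands of genes) the
guard is rarely triggered and the bare k = 20 default applies.

`compute_kinship()` builds the frequency-standardized similarity
matrix: dosages centred by `2p` and scaled by `sqrt(2p(1-p))`, missing
mean-filled, averaged over polymorphic sites — symmetric and positive
semi-definite by construction.

`knn_impute()` fills each missing dosage from the k = 3 nearest
accessions over a w = 80-site window (allele-sharing distance over
mutually called sites, >= 3 shared sites required, weights
`distance^p` with p = -7), only when the weighted vote for the winning
class reaches r = 0.8; the (w, k, p, r) grid of the original software
is exposed so the masking experiment (`evaluate_imputation()`, masking
10-30% of called cells) can compare combinations.  The original
implementation's exact distance and weighting are unpublished; this
contract is this package's definition.

`association_scan()` is the EMMAX-style two-step approximation: per
trait, the variance ratio delta = sigma_e^2/sigma_g^2 is estimated once
by REML under the null on the kinship eigenbasis (grid search plus
golden-section refinement over log delta in [-8, 8]), then every SV is
tested by generalized least squares with fixed covariance.  Sites are
pre-filtered to minor allele frequency >= 1% and missingness <= 40%;
residual missing dosages are mean-filled; zero-variance sites are
skipped.  With an identity kinship the scan reduces exactly to
ordinary linear regression (same t statistic and degrees of freedom).
`bonferroni_threshold()` supplies the alpha/m significance cutoffs.

`ld_background()` bins pairwise r^2 by distance (50-kb bins within
10 Mb), smooths with a short running mean, and calls the plateau where
the decay slope falls below 1% of its initial value; the background
level is the mean r^2 beyond that point and the background distance the
first distance at which the smoothed curve reaches it.  A curve with no
appreciable decay is all background; a curve with no plateau returns
the last bin with a warning.

`build_eqtl_blocks()` chains a gene's significant SVs left-to-right
when *adjacent* members (the stated grouping is between adjacent SVs,
not all pairs) have r^2 above the background level and distance below
the background distance; chains with >= 3 members become blocks with
the smallest-p member as lead (leftmost on ties).  A block is cis when
its lead SV — the lead, parameterizable, rather than any member — lies
within 50 kb of the gene's transcription start or stop site on the same
chromosome.  The output is invariant to input row order.

`detect_hotspots()` scores sliding 50-kb windows (25-kb step) by the
count of distinct genes whose trans lead SV falls inside, against a
one-sided Poisson tail at the genome-wide mean lead density, BH-adjusts
across all windows, keeps adjusted *P* < 0.05 and merges overlapping
significant windows.  The hotspot scanner named by the source is not
described in detail; this Poisson clustering test is the documented
stand-in.  `rank_master_regulator()` ranks, for each gene inside the
hotspot, all expressed genes by absolute Pearson correlation with it
and scores target-gene enrichment near the top by the minimal
hypergeometric tail over ranking prefixes ending at a target (the
iterative-group-analysis statistic); candidates are ordered by that
enrichment.

## Standard evaluation scenarios and their sizes

Three canned scenarios (see `?selection_scenario_config`) characterize
the pipeline's operating behaviour; their parameters are fixed study
conditions.

* *Selection*: four stages of 100 accessions, 200 loci, flat baseline
  A frequency 0.6 so null loci carry no frequency change, and 20 sweeps
  forced along 0.6 → 0.32 → 0.05.  Measured by
  `evaluate_selection_recovery()` (power and false-positive rate).
* *Introgression*: one 10-Mb chromosome, ~400 SVs, cultivated baseline
  A frequency 0.001 — below the archetype floor, so wild-like segments
  arise only from the planted block — and one introgression into 10% of
  modern accessions over 3–5 Mb.  Window recovery is scored with recall
  over windows fully inside the block and precision over windows
  overlapping it: a window overlapping the block by a sliver is
  majority background by construction and is correctly rejected.
* *eQTL*: 150 accessions (30/40/40/40), 2,000 SVs on two 10-Mb
  chromosomes (one SV per ~10 kb, so cis windows hold several linked
  SVs), 300 genes, 20 cis effects of 2.0 expression units per dose (the
  expression simulator's reference effect size), one hotspot (regulator
  effect 2.0, target weight 1.0).  The mosaic segment length is 500 kb
  here rather than the 2-Mb default: with 2-Mb segments on a 20-Mb toy
  genome the kinship matrix is nearly low-rank (a few dozen independent
  segments for 150 accessions), an extreme form of proximal
  contamination that erases mixed-model power; 500-kb segments flatten
  the kinship spectrum into the regime that real panels — twelve
  chromosomes, genome-wide markers — actually occupy.

These sizes keep each evaluation in seconds-to-minutes on a laptop
while preserving the statistical regime (strong local LD, strong stage
structure, high homozygosity) the methods assume.

## Known limitations

* Read evidence is idealized (no sequencing error, no mismapping, no
  CIGAR-I/D representation of small indels); genotyping accuracy on
  real alignments will be lower than the simulated recovery rates.
* The mosaic population model has no explicit pedigree, mutation, or
  recombination hotspots; LD is stationary along the chromosome.
* Hidden-factor correction uses principal components, not a variational
  factor model; with few genes the concentration guard is essential and
  with many genes factor choice is the user's responsibility.
* The hotspot test assumes lead SVs are Poisson under the null;
  clustered null leads (e.g., from residual structure) inflate it, which
  the BH adjustment only partly absorbs.
* Multi-allelic and nested SVs are not merged or specially resolved.
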