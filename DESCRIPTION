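Package: svdomest
Title: Structural-Variant Population Genomics and eQTL Mapping for Crop
    Domestication Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Validates and merges structural variants (SVs) called between a
    wild and a cultivated reference genome assembly, genotypes the merged SV
    set across a population from split-read and read-depth evidence, scans
    allele-frequency shifts across domestication stages with Fisher's exact
    tests under Bonferroni control, computes windowed nucleotide diversity
    and Weir-Cockerham F_ST, detects wild-donor introgressions from
    genotype-sharing ratios, and maps expression QTLs with an EMMAX-style
    linear mixed model, including LD-clustered eQTL blocks, cis/trans
    classification, trans-eQTL hotspot detection and iterative-group-analysis
    master-regulator ranking. A synthetic-data module generates toy genome
    pairs, population genotypes with drift, sweeps and introgression,
    read-level alignment evidence, and expression matrices with planted cis
    and trans effects, all with machine-readable truth, so the entire
    pipeline runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR,
    rtracklayer
Config/testthat/edition: 3
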