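Package: spacna
Title: Allele-Specific Copy Number and Clone Phylogeography from Spatial Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers allele-specific copy number aberrations, spatially coherent
    cancer clones, per-spot tumor proportions and a clone phylogeography from
    spot-level transcript counts and SNP allele counts (Visium-style spatial
    transcriptomics). Corrects population-phasing switch errors with a
    pseudobulk hidden Markov model with beta-binomial emissions, aggregates
    haplotype-aware counts into variable-length genomic bins, and jointly
    infers copy-number states along the genome (HMM) and clone labels over
    space (hidden Markov random field) by block coordinate ascent. Loss of
    heterozygosity regions drive a B-allele-frequency estimate of tumor purity
    and, as irreversible phylogenetic markers, a maximum-parsimony clone tree
    whose ancestral nodes are placed in physical space by a Gaussian diffusion
    model. Includes a synthetic-data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    data.table,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
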