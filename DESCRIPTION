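Package: ibdscan
Title: Runs of Homozygosity, IBD Segment Sharing and Case-Control
    Association for SNP Array Panels
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for case/control genetic analyses of
    congenital defects in livestock SNP-array data: PLINK text PED/MAP
    input and output, marker and sample quality control with an exact
    Hardy-Weinberg test and greedy LD pruning, IBS/IBD relatedness and
    classical MDS outlier screening, sliding-window detection of runs of
    homozygosity with FROH genomic inbreeding, pairwise shared-segment
    detection with a case/case label-permutation test, per-marker allelic
    chi-square association with odds ratios and genomic inflation, and
    EM-based multi-marker haplotype association. A pedigree gene-drop
    simulator with an implantable risk haplotype generates fully
    structured synthetic cohorts so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
biocViews: GenomeWideAssociation, SNP, QualityControl
Config/testthat/edition: 3
RoxygenNote: 7.3.3
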