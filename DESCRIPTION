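Package: mrclone
Title: Multi-Region Subclonal Evolution Analysis for Mouse Tumor Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs the subclonal architecture of multi-region sequenced
    mouse pancreatic tumors. Implements qPCR standard-curve purity estimation,
    purity-corrected integer copy number from array-CGH log ratios with focal
    and large-scale somatic copy-number calling, simulation-calibrated
    allelic-imbalance detection from germline heterozygous SNPs, read-count
    based cancer-cell-prevalence estimation on a binomial grid with
    multiplicity resolution, density-based prevalence clustering, and
    exhaustive constrained enumeration of subclone hierarchies with
    linear/branched topology classification. A synthetic-cohort generator
    emulating the multi-region study design (three tumor regions per mouse,
    amplicon read counts, probe-level log ratios, het-SNP counts, qPCR
    standards) provides ground-truthed inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    cluster,
    ape,
    Rcpp,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
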