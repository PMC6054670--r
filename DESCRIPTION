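Package: lohscape
Title: Tumor/Normal Copy-Number, Loss-of-Heterozygosity and Dosage-Expression Karyotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers tumor karyotypes from paired tumor/normal sequencing
    summaries: germline heterozygous sites are detected with an exact binomial
    criterion on allelic read counts, genome tiles are converted to normalized
    log2 coverage ratios and segmented by permutation-based circular binary
    segmentation, and segment copy number and loss of heterozygosity (LoH) are
    called under an explicit tumor-purity mixture model. Per-autosome dominant
    copy number and LoH calls are rolled up into cohort aneuploidy summaries,
    recurrent-LoH pattern mining and a three-group tumor classification with
    exact tests of clinical association. Somatic variants are filtered by
    depth/support/blacklist rules, germline variants rendered unopposed by
    somatic LoH are flagged, and biallelic gene inactivation is called.
    Chromosome- and segment-scale copy-number dosage effects on expression are
    quantified after batch centering and Z-scoring. A synthetic-cohort
    generator with known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    withr,
    vcfR,
    GenomicRanges,
    IRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
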