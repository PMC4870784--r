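Package: xiseq
Title: Allele-Specific Analysis of X-Chromosome Inactivation from Sequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the establishment and maintenance of X-chromosome
    inactivation from allele-resolved sequencing assays. Implements Xi/Xa
    allelic-ratio analysis of exonic SNP counts with a rule-based reactivation
    classifier, windowed Poisson broad-domain peak calling against a histone H3
    control with bin-coverage correlation and allele-split peak enrichment,
    allele-aware differential DNA methylation at CpG islands from bisulphite
    CpG calls, rule-based gene-silencing classification relative to Setdb1
    peaks, repeat-class enrichment testing, a pooled shRNA screen readout with
    conditional exact testing, and 1-D immunofluorescence cross-section peak
    finding. A synthetic-data generator with planted ground truth drives
    parameter-recovery and null-calibration tests for every stage.
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
    edgeR,
    data.table,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
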