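Package: pedsqtl
Title: QTL-seq and Linkage Mapping of Single Versus Paired Spikelets in
    Maize x Teosinte Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-pronged genetic analysis of the percentage of cupules with a
    single spikelet (PEDS), the key ear trait separating teosinte from maize,
    in advanced backcross (BC3F2/BC4F2) maize x teosinte populations. One arm
    is QTL-seq bulked-segregant analysis: per-SNP SNP-index with depth
    filtering, sliding-window averages, delta(SNP-index) between extreme
    phenotype bulks, Monte-Carlo null confidence bands, and threshold-based
    candidate-region calling. The other arm is local linkage mapping:
    segregation-distortion screening, two-point recombination estimation with
    Kosambi distances, and inclusive composite interval mapping for single-QTL
    (additive/dominance) and two-locus additive-by-additive epistasis scans.
    A forward simulator of the recurrent-selection backcross scheme, with a
    censored polygenic PEDS phenotype and pooled allele-depth sequencing,
    provides fully synthetic inputs so the complete pipeline is testable
    without field or sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
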