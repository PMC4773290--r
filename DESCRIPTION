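Package: regulocal
Title: Localisation of Functional Regulatory Variants at GWAS Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A post-GWAS workflow for localising functional non-coding
    variants at a trait-associated locus: linkage-disequilibrium based
    candidate selection around a lead SNP, marginal cis-eQTL scanning,
    Bayesian trait-expression colocalisation from summary statistics via
    approximate Bayes factors, overlap classification of variants against
    regulatory-annotation tracks, allele-specific chromatin-accessibility
    (FAIRE) imbalance statistics from genotyping-array B-allele
    frequencies, and allele-specific EMSA probe design. Includes a
    haplotype-block locus simulator with known ground truth so the whole
    pipeline is testable end to end without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
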