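Package: bsaqtl
Title: Bulked Segregant Analysis Sequencing for Major-Effect Locus Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for mapping major-effect loci in biparental
    F2 populations by bulked segregant analysis of whole-genome sequencing
    data (BSA-seq). Implements Mendelian segregation testing with Wilson
    score confidence intervals, three per-site bulk association statistics
    (delta SNP-index, the G likelihood-ratio statistic with tricube
    smoothing into G', and the Euclidean distance between bulk allele
    frequencies raised to the fourth power), sliding-window genome scans
    with empirical quantile thresholds and candidate-interval calling,
    recombinant-breakpoint fine-mapping under a dominance model, and
    genotyping-marker selection. A seedable F2 meiosis and bulk-sequencing
    simulator generates realistic parent-plus-bulk variant tables so every
    stage of the pipeline can be exercised and validated without external
    data. Variant input is read from VCF or a plain tab-separated dialect.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
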