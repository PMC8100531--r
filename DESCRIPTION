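Package: cryopiR
Title: Comparative piRNA Profiling of Fresh and Frozen-Thawed Sperm Small RNA Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully testable pipeline for comparative
    PIWI-interacting RNA (piRNA) analysis of small RNA sequencing libraries
    from fresh versus frozen-thawed sperm in two species. Provides a
    synthetic-data generator with planted truth (toy genomes, piRNA clusters
    with 5'-uridine bias, ncRNA contamination, negative-binomial expression
    shifts), adapter trimming and two-stage length/quality filtering, ncRNA
    read removal, exact substitution-only genome mapping, density-based
    piRNA cluster detection, sequence-level TPM quantification, a
    no-replicate negative-binomial exact test for differential expression
    with Benjamini-Hochberg adjustment, a 5'-anchored cross-species piRNA
    homology matcher that partitions differentially expressed piRNAs into
    common and species-unique sets, antisense seed-based target prediction,
    and hypergeometric GO/KEGG over-representation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    methods,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    DESeq2,
    IRanges,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
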