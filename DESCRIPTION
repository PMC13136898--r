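Package: pgsplice
Title: Proteogenomic Identification of Translated Alternative Splicing Events
Version: 0.1.0
Authors@R:
    person("pgsplice", "developers", email = "pgsplice@example.org",
           role = c("aut", "cre"))
Description: A proteogenomic toolkit for detecting translated alternative
    splicing (AS) isoforms. Builds transcript models from GFF3 annotation
    and a genome FASTA, enumerates a SUPPA-style catalog of AS events
    (intron retention, exon skipping, alternative 5'/3' splice sites,
    alternative first/last exons, mutually exclusive exons), filters
    search-engine peptide tables down to isoform-specific peptides,
    projects peptides onto genomic coordinates with junction-spanning
    flags, and calls proteomically supported events. Computes intron
    read-depth ratios (IDratio) from RNA-seq coverage, selects
    unannotated retained-intron candidates, translates them into an
    expanded protein database, and post-processes quantitative
    proteomics matrices (protein-group selection, downshifted-normal
    imputation, differential thresholds, increased-intron-retention
    calls, and peptide positioning relative to retained introns).
    Ships a deterministic synthetic-fixture generator with ground-truth
    manifests so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    data.table,
    jsonlite,
    stats,
    utils,
    rtracklayer,
    S4Vectors,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
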