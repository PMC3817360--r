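Package: divergescan
Title: Candidate-Gene Prioritization in QTL Regions of Divergently Selected Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate genes and mutations within mapped QTL
    regions of two divergently selected populations. Estimates between-line
    genetic divergence from pooled resequencing read counts (AB scores and
    flanking-SNP values) and from individual SNP-chip genotypes, fuses these
    with a normalized QTL support curve into a combined data score (CDS),
    selects high-divergence candidate segments, annotates variants against
    gene models and CpG islands, filters genes by growth-related annotation
    keywords, and scores amino-acid substitutions by physicochemical
    difference and evolutionary conservation. Includes a Wright-Fisher
    forward simulator of divergent truncation selection so the whole
    pipeline can be exercised on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
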