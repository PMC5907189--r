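Package: methlift
Title: Cross-Species Methyl-Capture Target Redefinition and Methylome Summaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Adapts a human methyl-capture sequencing panel to non-human primate
    genomes. Redefines the capture target as the homologous probe region (HPR,
    from identity/e-value filtered probe alignments) plus the orthologous
    promoter region (OPR, from gene-symbol matched promoters covered by probes),
    builds the CpG island/shore/shelf/promoter/intragenic region taxonomy with a
    running-score island detector, and summarises bisulfite cytosine reports
    into strand-merged CpG calls, on-target depth statistics and per-region
    methylation levels. Includes a deterministic synthetic-study generator with
    a beta-binomial methylation model for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
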