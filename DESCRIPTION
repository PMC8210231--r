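Package: ncrmscreen
Title: Screening of Candidate Non-Coding Recurrent Mutations in Cancer Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies candidate cancer-related non-coding recurrent
    mutations (CNRMs) from somatic mutation catalogs. Implements a ten-step
    filtering cascade (tissue/individual/somatic/SNP source filters, exon
    exclusion, cross-sample and cross-cancer-type recurrence, cross-cohort
    position intersection, and overlap with open-chromatin peaks, chromatin
    interaction anchors and transcription-factor binding sites), a
    Shannon-entropy-based motif impact statistic (delta-bit) with resampled
    expectation, resampling enrichment nulls, and a z-score-integrated
    Wilcoxon/Benjamini-Hochberg screen that associates binding-site mutations
    with target-gene expression. Includes a seeded synthetic-cohort generator
    with a planted-truth manifest so the full pipeline can be exercised and
    validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
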