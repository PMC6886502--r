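Package: apexatlas
Title: Expression Atlas Analytics for the Maize Shoot Apex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for laser-microdissection RNA-seq atlases of
    the maize shoot apex: reads-per-million normalization, Shannon-entropy
    domain-specificity scoring, negative-binomial exact-test differential
    expression, CAST profile clustering into meristem functional-domain
    archetypes, transcription-factor family principal-component analysis,
    promoter position-weight-matrix scanning with exact threshold
    calibration and motif-enrichment network construction, and
    divergence-from-expectation enrichment statistics for binding-target
    and trait-associated-SNP gene sets. Includes a fully specified
    synthetic-atlas generator with planted ground truth so the complete
    pipeline is exercisable and testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
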