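Package: nascentUV
Title: Nascent Transcription Responses to UV Damage from Bru-Seq Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Downstream analysis of nascent RNA sequencing (Bru-seq) time
    courses after UVC irradiation. Computes gene-body RPKM, applies biological
    scaling normalisation with externally measured global-transcription
    correction factors, classifies UV-repressed and UV-induced genes, calls
    fast versus slow repression kinetics, assigns knockdown-dependency classes
    for transcription recovery, models the expected UV lesion load per
    transcription unit as a Poisson process along gene bodies, intersects
    ChIP-seq peaks with promoter-extended transcripts, and tests gene-list
    overlaps with Fisher's exact test. Includes a synthetic-data generator
    with planted truth so every pipeline stage can be validated by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
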