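Package: driptrc
Title: DRIP-Seq Signal Enrichment at Transcription-Replication Conflicts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide quantification of R-loop (DRIP-seq) signal at
    transcription-replication conflict regions. Bins aligned reads into
    100-nt windows, normalizes to a 10M-read library scale, aggregates the
    signal over strand-oriented windows anchored on replication origins
    inside transcribed gene bodies, splits head-on from co-directional
    collision sub-windows, and tests sample-versus-control enrichment with
    Fisher's exact test and Bonferroni correction, with bootstrapped
    metaprofiles and ECDF summaries. A synthetic-data generator with known
    orientation-restricted enrichment makes the whole pipeline testable
    without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
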