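Package: itss
Title: Detection of Condition-Specific Internal Transcription Start Sites
    from RNA-Seq Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Detects transcription start sites that appear inside annotated
    open reading frames when comparing per-base RNA-seq coverage of test
    samples against a control. Coverage tracks are Gaussian-smoothed and
    depth-normalized, compared in sliding windows by the root mean squared
    deviation of area-normalized curves, and shape-difference peaks are
    filtered against transcription-end-site confounders and percentile
    thresholds before being assembled into ranked transcript contigs.
    Contigs supported by several samples are combined into consensus calls,
    classified as ORF-internal start sites, and scanned for promoter motifs
    (position weight matrices) with an exact enrichment test. Includes a
    synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
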