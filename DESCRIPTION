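Package: acetrace
Title: Gene-Signature Screening of Raw Metagenome Reads and SEC
    Protein Correlation Profiling
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects signatures of acesulfame-degradation genes (sulfatase
    and acetoacetamide-N-sulfonate amidase) directly in raw shotgun
    metagenome and metatranscriptome reads, using percent-identity and
    query-coverage match criteria with rescue of reads that straddle gene
    termini via genomic flanking sequence, and aggregates per-dataset
    detections into site-per-year counts with detection-rate and
    size-correlation statistics. A second component links an enzymatic
    activity elution profile from size-exclusion chromatography (SEC) to
    protein abundance profiles by hierarchical correlation clustering,
    calibrates apparent molecular masses, and ranks oligomeric-state
    candidates. Synthetic-data generators (genes, homolog decoys,
    error-bearing reads with truth labels, multi-site surveys, SEC
    experiments with planted correlated proteins) make the whole pipeline
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
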