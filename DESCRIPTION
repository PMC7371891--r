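Package: mutdiff
Title: Relative Mutational Difficulty for Somatic Coding Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates sequence-context-specific somatic mutation tendencies
    from large cancer mutation catalogs and converts them into relative
    mutational difficulty scores. Each single-nucleotide substitution is
    binned by its pentanucleotide context (the mutated base plus two
    flanking bases on either side) and its alternate allele, giving 3072
    mutation classes whose per-site, per-genome rates differ by several
    hundred fold. Observed recurrence of a coding mutation is then
    re-weighted by cancer-type-specific difficulty to produce a "revised
    count" that separates loss-of-function from wild-type-like mutations,
    with thresholds calibrated on synonymous mutations. Also evaluates
    synonymous codon recoding that shields mutation hotspots, and ships a
    synthetic catalog generator with known class rates and driver
    enrichment for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
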