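Package: rDNAge
Title: Age-Dependent Ribosomal DNA Copy Number, Methylation and Variant Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of age-dependent changes in the ribosomal
    DNA (rDNA) repeat array of mouse bone marrow cells. Implements absolute
    copy-number quantification from droplet digital PCR partition counts via
    Poisson inversion, single-cell qPCR copy-number estimation against a
    calibrated standard curve, copy-number estimation from whole-genome
    sequencing read fractions, per-position mutation-rate tracks from amplicon
    pileups with a control-gene artifact threshold and age-differential site
    calling, 20-bp window mutation hot-spot mapping, in-silico restriction
    digestion with methylation-sensitive enzymes and the derived band-intensity
    ratio statistics, housekeeping-normalized relative expression, and yeast
    chronological life-span survival curves. A seeded synthetic-cohort
    generator reproduces the statistical structure of young/old two-strain
    mouse data so the full pipeline runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    Rsamtools,
    Biostrings
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
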