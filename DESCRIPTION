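Package: xorgan
Title: Cross-Species Organ Transcriptome Comparison
Version: 0.1.0
Authors@R: person("Endostyle", "Analytics", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing organ transcriptomes across species through
    homolog maps: organ-specific gene (OSG) calling for a focal organ against
    a reference organ panel, projection of OSGs onto a target species' organs
    as per-organ similarity ratios, tissue-enriched gene classification and a
    similarity index against an expression atlas, shared/organ-only expressed
    gene partitions with hypergeometric over-representation testing, unit
    conversions (counts to TPM/FPKM/RPKM), pseudobulk aggregation,
    replicate-level quality control, and a synthetic two-species data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
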