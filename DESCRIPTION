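Package: suborders
Title: Mining Ordinal Suborders and Alternative Progressions in Labeled Molecular Data
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects total and partial ordinal class structures in labeled
    high-dimensional molecular data (bulk and single-cell transcriptomics).
    Samples are projected onto one dimension along the normal of a
    deterministic max-margin linear classifier trained on a chosen class
    pair; directed threshold classifiers are then arranged into ordinal
    classifier cascades and all candidate class sequences are screened
    under a class-wise sensitivity floor with early rejection and
    pairwise-classifier reuse.  Surviving maximal suborders are merged
    into layered alternative-progression graphs via a shared-threshold
    equivalence calculus, and detected structures can be cross-checked
    with an independent monotone separability-matrix validator.  Includes
    a synthetic-data generator with known ground-truth branching
    structure and a command-line style driver for the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
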