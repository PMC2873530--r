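Package: deimmune
Title: Globally Optimal Epitope-Deletion Design for Protein Deimmunization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design tools for reducing the predicted MHC class II (HLA-DR)
    T-cell epitope content of therapeutic proteins. Every 9-mer window of a
    target sequence is scored with additive pocket-profile matrices against
    per-allele percentile thresholds; per-position allowed substitutions are
    derived from BLOSUM-62, tree-weighted family conservation, or an external
    ddG substitution scan; and a dynamic program over 8-mer suffix states
    finds provably optimal and near-optimal substitution sets minimizing the
    total predicted epitope count, optionally under a substitution budget.
    Includes exact threshold calibration by score-distribution convolution,
    brute-force oracles, multi-metric variant reports, and deterministic
    synthetic fixtures for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
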