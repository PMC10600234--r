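Package: binderscore
Title: Evaluation and Selection of Designed Peptide Binders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometry-based evaluation of designed peptide and miniprotein
    binders against receptor structures predicted with AlphaFold2-style
    tools. Implements the 8 Angstrom beta-carbon interface definition,
    receptor C-alpha superposition and binder interface RMSD, a
    plDDT-weighted bind-score loss combining directed interface distances
    with a centre-of-mass displacement term, contiguous backbone seed
    cropping by interface contact count, amino-acid-category contact
    recovery and interface sequence recovery, mutation scans, and
    campaign-level analytics (ROC/AUC binder selection, success-rate
    convergence, specificity summaries, contact-density profiles).
    Includes a synthetic complex generator so every metric is testable
    without external structure downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
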