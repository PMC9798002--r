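Package: mieeg
Title: Inter-Electrode Interaction Features for Motor-Imagery EEG Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying whether inter-electrode interaction features
    (Pearson correlation or a generalized, dot-product Jaccard distance)
    added to sliding-window band-power features improve two-class
    motor-imagery EEG classification. Provides a synthetic multi-subject
    EEG cohort generator emulating a three-channel (C3, Cz, C4) feedback
    paradigm at 250 Hz, sliding-window feature extraction (mu and beta band
    powers plus pairwise interaction measures), a shared-covariance linear
    discriminant classifier, a linear-chain hidden conditional random field
    with disjoint per-label hidden-state sets trained by maximum conditional
    likelihood, a nested cross-validation protocol, and randomized-blocks
    ANOVA with Tukey-Kramer post-hoc comparisons over blocked accuracy
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
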