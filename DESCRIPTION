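Package: spectanom
Title: Spectral Coherence Abnormality Analysis for Resting-State Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how atypical the frequency-resolved functional
    connectivity between two brain regions is for each subject in a cohort.
    Region signals are extracted from 4D NIfTI volumes (or loaded from
    tables), modelled with a bivariate vector autoregression fitted by
    Yule-Walker with AIC lag selection, and summarised as parametric
    magnitude-squared coherence on a fixed frequency grid. A nu-parameterised
    one-class support vector machine trained on the pooled cohort converts the
    coherence features into a per-subject abnormality index; a
    leave-one-frequency-out retraining procedure scores the discriminative
    relevance of each frequency, and rank-based tests compare the index
    between groups. A synthetic cohort generator with band-localised
    cross-coupling and a Welch coherence oracle make the whole pipeline
    testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
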