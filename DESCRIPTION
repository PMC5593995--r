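Package: mipscsf
Title: Cerebrospinal Fluid Volumetry and Magnetic Induction Phase Shift
    Analysis for Hematoma Expansion Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking cerebrospinal fluid (CSF) volume loss
    to magnetic induction phase shift (MIPS) signal change during
    intracerebral hematoma expansion. Conditions raw MIPS phase recordings
    into block-smoothed, baseline-normalized series; segments CSF from
    T2-like magnetic resonance volumes by fuzzy c-means clustering with
    Markov random field spatial regularization, template masking and voxel
    volumetry; synchronizes the two modalities on injected blood volume; and
    runs the statistical battery (multiple regression with ANOVA, partial
    correlations, derivative-curve correlation) together with reversal-point
    detection on the smoothed signal. A synthetic-data generator produces
    MIPS recordings, piecewise-linear CSF compensation trajectories and MR
    phantoms with ground truth so the whole pipeline is testable without
    animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
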