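Package: lcrelax
Title: Quantitative MR Relaxometry of the Locus Coeruleus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for multi-flip-angle quantitative
    MR relaxometry of the locus coeruleus (LC). Provides steady-state forward
    models for SPGR, phase-cycled bSSFP and the double-angle B1 method in
    single- and two-component (non-exchanging) form; voxel-wise DESPOT1/DESPOT2
    estimation of R1 and R2 and Bayesian Monte-Carlo estimation of the myelin
    water fraction; rostro-caudal slice profiling and subregion summaries of LC
    masks including the dilated-shell and shifted-mask sensitivity constructs;
    neuropsychological domain z-scoring; and the cross-sectional and
    longitudinal (random-intercept mixed model) statistical models linking LC
    microstructure to age and cognition, with Benjamini-Hochberg FDR control.
    A synthetic-data module generates LC-like phantoms with ground-truth
    parameter gradients and longitudinal cohorts with the generative structure
    the statistical models assume, so the whole pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    yaml,
    jsonlite,
    lme4,
    lmerTest
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
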