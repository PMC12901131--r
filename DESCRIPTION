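Package: visood
Title: Synthetic Visual Stimuli and Out-of-Distribution Evaluation of
    fMRI Encoding Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building out-of-distribution (OOD) generalization
    tests of voxelwise fMRI encoding models. Provides a deterministic
    generator for a 284-image synthetic stimulus set (noise, scenes and
    manipulated scenes, contrast- and phase-coherence-modulated scenes,
    single words, log-polar spiral gratings, and isoluminant chromatic
    noise), a builder for the matching event-related trial/run/session
    design with fixation and one-back tasks, behavioral scoring (percent
    correct and d-prime), noise-ceiling signal-to-noise ratio (NCSNR)
    estimation and noise-ceiling conversion, feature-based encoding models
    (PCA plus per-vertex linear or cross-validated ridge regression) with
    noise-ceiling-normalized scores, OOD evaluation machinery (classical
    multidimensional scaling, distributional distances, zero-shot image
    identification, representational similarity analysis, k-means based
    train/ID/OOD split construction), and a synthetic response simulator
    with known ground truth for validating every stage of the pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
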