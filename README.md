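# visood

Out-of-distribution (OOD) generalization tests for voxelwise fMRI encoding
models, end to end: a parametric generator for a 284-image synthetic
stimulus set, the matching event-related session design, behavioral
scoring, noise-ceiling estimation, encoding-model fitting and evaluation,
and the OOD analysis stack — validated on simulated responses with known
ground truth.

## The problem

Encoding models predict per-vertex brain responses from stimulus features,
`y_v = f(x)·w_v + ε`. Trained and tested on photographs from one
naturalistic distribution, competing models often look indistinguishable;
their failures surface only out of distribution. Testing OOD needs three
ingredients this package provides:

* **Stimuli far from the naturalistic distribution.** A deterministic
  generator renders 284 images in 71 subclasses and 8 classes: white/pink
  noise, natural and manipulated scenes (upside-down, Mooney, line-drawing
  substitute), contrast modulation (100–4%), phase-coherence modulation
  (75–0% — phase blended with a random spectrum while the amplitude
  spectrum is preserved exactly), single words at five positions, 112
  log-polar spiral gratings whose local spatial frequency is `L/(2πE)`
  cycles/degree at eccentricity `E`, and isoluminant chromatic noise at 16
  hues. Geometry: 1360 × 714 px spanning 16° × 8.4° (85 px/degree).
* **Reliability accounting.** The noise ceiling signal-to-noise ratio
  (NCSNR) `s = σ_signal/σ_noise` is estimated per vertex from repeated
  presentations, and converted to the noise ceiling
  `NC = 100·s²/(s² + 1/n)` — the percentage of variance in n-repeat
  averaged responses that any model could explain. Model scores are
  divided by NC so ID and OOD performance are comparable despite different
  noise levels.
* **Degree-of-OOD quantification.** Responses are embedded in 2-D by
  classical MDS; each test class's mean Euclidean distance to the training
  responses measures how far out of distribution it is, and is related to
  per-class model performance (Spearman ρ per participant, one-sample
  t-test across participants). Zero-shot identification ranks each
  recorded pattern's correlation with model-predicted patterns among
  candidates; k-means on the embedding builds train/ID/OOD splits from
  within a single dataset.

A response simulator with known tuning, target NCSNR, session offsets and
plantable OOD structure (readout rotation or off-manifold shift) provides
ground truth for every stage.

## Worked example

```r
library(visood)

# 8-run session: 107 trials/run, tasks XOXOXOXO over designs ACBDCADB
session <- assemble_session(seed = 1)
session
#> session design: 8 runs (tasks XOXOXOXO, designs ACBDCADB), 744 stimulus trials, 80 one-back

# behavioral scoring of a simulated 90%-accurate observer on run 1's dots
dots <- session$runs[[1]]$dots
presses <- simulate_fixation_presses(dots, p_correct = 0.9, seed = 2)
score_fixation(dots, presses)
#> fixation task: 89.1% correct (212/238 changes)

# simulated responses: 50 vertices at NCSNR 1.5, one class rotated off-readout
feats <- matrix(rnorm(284 * 30), 284, 30)
cls <- c(rep("id", 142), rep("ood", 142))
sim <- simulate_responses(feats, n_vertices = 50, ncsnr = 1.5, repeats = 3,
                          class_of = cls, ood_rotation = c(ood = pi/3), seed = 3)
s_hat <- compute_ncsnr(sim$responses)
median(s_hat)                             # 1.50  (truth: 1.5)
median(ncsnr_to_noise_ceiling(s_hat, 3))  # 87.1  (% explainable variance)

# encoding model trained on half the in-distribution images
avg <- average_by_image(sim$responses)
m <- fit_encoding(feats[1:100, ], avg[1:100, ], n_components = 30)
nc <- ncsnr_to_noise_ceiling(s_hat, 3)
id  <- evaluate_encoding(m, feats[101:142, ], avg[101:142, ], nc = nc)
ood <- evaluate_encoding(m, feats[143:284, ], avg[143:284, ], nc = nc)
median(id$nc_normalized)   # 0.94 — near the noise ceiling in-distribution
median(ood$nc_normalized)  # 0.25 — the planted OOD rotation breaks the readout
```

The rotated class retains full signal (same NCSNR) yet the trained readout
explains only a quarter of its explainable variance: exactly the signature
an OOD generalization test is built to expose.

Rendering the stimulus set:

```r
set <- build_full_set(seed = 1)   # 284 images, ~20 s
set
#> stimulus set: 284 images, 71 subclasses, 8 classes (seed 1)
export_stimulus_set(set, "stimuli/")   # PNGs + manifest.csv
```

## Documentation

The methods vignette (`vignettes/visood-methods.Rmd`) describes the models
and procedures, every tunable parameter with its default and rationale,
what the simulator does and does not emulate, numerical choices, and known
limitations.
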