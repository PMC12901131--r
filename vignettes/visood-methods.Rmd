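---
title: "Methods: synthetic stimuli, reliability estimation, and out-of-distribution evaluation of encoding models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic stimuli, reliability estimation, and out-of-distribution evaluation of encoding models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(visood)
```

## Scope and rationale

Voxelwise encoding models — linear readouts from stimulus features to
per-vertex fMRI response amplitudes — are almost always trained and tested
on naturalistic photographs drawn from one visual distribution. A model can
score well in-distribution (ID) while failing badly on images outside that
distribution, so out-of-distribution (OOD) tests are the sharper instrument
for model comparison. `visood` implements the full computational stack for
such tests:

1. a parametric generator for a 284-image synthetic stimulus set spanning
   eight image classes (noise, scenes, manipulated scenes, contrast
   modulation, phase-coherence modulation, single words, log-polar spiral
   gratings, chromatic noise);
2. a builder for the matching event-related session design (eight runs,
   alternating fixation and one-back tasks);
3. behavioral scoring for both tasks (percent correct; d′);
4. reliability estimation via the noise ceiling signal-to-noise ratio
   (NCSNR) and its conversion to noise-ceiling variance fractions;
5. encoding models (feature extraction → PCA → per-vertex regression, or
   cross-validated ridge) with noise-ceiling-normalized scores;
6. OOD evaluation machinery: MDS embeddings, distributional distances,
   zero-shot identification, RSA, and cluster-based train/ID/OOD splits;
7. a response simulator with known ground truth that exercises every stage.

Real fMRI recordings are deliberately out of scope: the package starts from
beta-like response matrices (trials × vertices), and its validation rests on
simulation with known ground truth plus the arithmetic of the stimulus and
design registries.

## Display geometry and the stimulus generator

All stimuli are rendered on a canvas of 1360 × 714 pixels spanning
16° × 8.4° of visual field, i.e. 85 pixels per degree; most content lives in
the central 714-pixel square, with mid-gray (0.5) flanks. Luminance is
represented physically in [0, 1]; an export lookup table maps it to RGB with
warm-white maximum (252, 220, 216) only at write-out.

Generator conventions worth knowing:

* **White noise** is blockwise Uniform(0, 1); the large-block variant uses
  42-pixel blocks, which tile the central square exactly (714 = 17 × 42).
  For non-divisor block sizes, partial edge blocks receive their own draw.
* **Pink noise** multiplies the Fourier transform of white Gaussian noise by
  a 1/f amplitude spectrum with the DC term zeroed, then maps mean ± 3.5 SD
  linearly to [0, 1]. The clipped fraction is recorded on the image, never
  silently discarded.
* **Scene preparation** applies, strictly in order: grayscale conversion,
  center square crop, bilinear resize to 714², display-gamma conversion
  (squaring on [0, 1]), and contrast normalization mapping the 0.1/99.9
  percentiles to [0, 1]. A constant image raises a degenerate-normalization
  error rather than producing an all-gray stimulus.
* **Mooney images** binarize at the median with ties mapping to white; this
  tie rule makes the operator idempotent and deterministic.
* **Phase-coherence blending** interpolates each frequency's phase along the
  shortest circular arc between the original and a random phase spectrum
  drawn from the Fourier transform of white noise (hence Hermitian, hence a
  real result), with self-conjugate bins pinned to their original phase.
  This choice keeps the amplitude spectrum exactly intact before the final
  clip to [0, 1] and minimizes clipping. An alternative reading —
  complex-vector averaging of the two spectra — would shrink amplitudes at
  intermediate coherences and was rejected for that reason.
* **Spiral gratings** are `0.5 + 0.5·cos(A·ln E + B·θ + φ)` with
  `A = L·cos(α)`, `B = round(L·sin(α))` and `(A, B)` renormalized to length
  `L` after rounding. The integer angular frequency removes the seam at
  θ = 0, and the renormalization preserves the local spatial-frequency law
  `L/(2πE)` cycles/degree exactly, so all mixing angles α share one SF map.
  The letter-to-angle assignment (A–D at π/2, π/4, 0, −π/4 — pinwheel,
  forward spiral, annulus, reverse spiral — and E–H at the four
  intermediate angles) is a package convention; only the angle set, not the
  lettering, is contractual, and `make_spiral_grating()` accepts any angle.
  Central cutouts of diameter {4, 8, 14, 26, 48, 86} px for levels
  L = {6, 11, 20, 37, 69, 128} avoid aliasing near the fovea.
* **Words** are rendered from a built-in 5 × 7 monospaced bitmap font
  (black on gray), scaled to x-heights of 0.4° (4-letter) and 0.27°
  (6-letter) with 0.43°/0.28° letter spacing, at positions −6°…6° along the
  horizontal meridian. A bitmap font keeps rendering deterministic and free
  of system font dependencies; every glyph has ink in its outermost columns
  so a word's ink bounding box is centered on its nominal position. The
  packaged word lists (20 four-letter, 20 six-letter common nouns) are a
  default, not a contract.
* **Chromatic noise** uses a generic isoluminant opponent plane: constant
  luminance 0.5, two chroma channels modulating along one of 16 evenly
  spaced hue angles, saturation proportional to a reduced-contrast pink
  noise base pattern and capped at a configurable gamut radius (default
  0.35). This is a synthetic stand-in for a display-calibrated cone-opponent
  chromaticity plane: without measured display spectra and cone
  fundamentals, only the geometry (even hue spacing, antiparallel opposite
  hues, isoluminance) is reproduced, not colorimetry. The hue-angle origin
  is likewise a convention.
* **Line drawings** are a labeled substitute: Sobel gradient magnitude
  thresholded at its 90th percentile, rendered as black strokes on gray,
  standing in for artist-traced contours that cannot be generated
  procedurally.
* **Scene sources** default to procedural fixtures (1/f background plus
  geometric occluders). They emulate the 1/f spectral statistics and
  occlusion structure of photographs but none of their semantics; passing
  tests on them demonstrates the pipeline's mechanics, not photographic
  realism. User photographs can be supplied instead.

Determinism: stochastic subclasses (noise, phase scrambles, chromatic bases)
derive from the set seed; scene fixtures use a separate `scene_seed`
defaulting to a fixed value, so regenerating with a different set seed
changes only the genuinely stochastic subclasses — mirroring the fact that
photographs are fixed inputs, not draws.

## Session design

Each trial lasts 4 s. A run is 107 trials (428 s): 3 leading and 4 trailing
blanks, 7 interior blanks, and 93 stimulus trials (83 base + 10 one-back
inserts). Base orderings place 268 single-presentation images once and the
16 scene-class images (subclasses 4–7) four times — 332 base trials split
into four 83-trial runs, rejection-sampled until no image repeats
back-to-back within a run. One-back inserts duplicate 10 distinct base
trials immediately after their source; an insert cannot itself receive an
insert, and blanks are placed after insertion, so an insert is always the
immediate successor of its source. Interior blank placement draws the eight
stimulus-streak lengths i.i.d. from {9…14} until they sum to 93, which
samples uniformly over admissible compositions. The session runs the four
designs as ACBDCADB under task order XOXOXOXO, so each design letter occurs
once per task with identical trial sequences — brain-activity differences
between tasks cannot be stimulus-driven. The fixation dot draws a luminance
level from {0.17, 0.37, 0.58, 0.79, 1} at t = 0 and every 1.4 s thereafter
(306 states per run), repeats allowed; the initial level's rule is a
package choice.

A consequence of random insert placement worth noting: the partition of the
284 images over total presentation counts (including inserts) varies with
the seed; only the totals (332 base, 372 including inserts, per task) and
the base partition (268 × 1, 16 × 4) are seed-invariant, and only those are
asserted.

## Behavioral scoring

Fixation: the first press within (0, 1.4 s] of each dot change scores
correct iff button 1 follows a decrement or button 2 an increment; no press
is incorrect. Changes where the level repeats have no correct answer and
are excluded from both numerator and denominator — the alternative
(counting them as incorrect) would bound percent correct by the repeat rate
(1/5 of changes) rather than measuring the observer. One-back: first press
within (0.25 s, 4.25 s] of stimulus onset, first stimulus trial of each run
excluded; one-back trials are signal-present (button 2 = hit), everything
else signal-absent, no press incorrect in both cases; rates are clipped to
[0.01, 0.99] before d′ = Φ⁻¹(hit) − Φ⁻¹(fa), bounding d′ to ±4.653. Windows
are open at the start and closed at the end, so a press at exactly the
window boundary counts.

## Reliability: NCSNR and the noise ceiling

Per vertex, betas are z-scored within each session (switchable — z-scoring
also rescales genuine signal, and session-effect analyses may want it off),
then the noise variance is the mean unbiased variance across repeats over
all images with ≥ 2 repeats, the signal variance is total minus noise
variance floored at zero, and NCSNR `s` is their SD ratio. The noise
ceiling for n-repeat-averaged responses is `NC = 100·s²/(s² + 1/n)`; with
unequal repeat counts, `n` is the harmonic mean of per-image repeats
(`effective_repeats()`), the standard treatment for mixed designs. Vertex
selection is by strict inequality (`s > 0.6` and noise-ceiling fraction
`> 0.3` are the conventional thresholds).

## Encoding models

Inputs are preprocessed as model rasters: center square crop, 224² bilinear
resize, optional square-root transform (applied to luminance-coded
synthetic images so their intensity statistics match gamma-encoded
photographs), scaling to [0, 1], and channel standardization with mean
(0.485, 0.456, 0.406), SD (0.229, 0.224, 0.225). The packaged feature
extractor is a weight-free multiscale oriented-energy bank (one-sided
log-Gabor quadrature energy at four scales × four orientations, mean-pooled
on a 7 × 7 grid); any deterministic callable satisfying the
`feature_extractor()` contract can replace it, so pretrained-network
activations plug in where available without changing the pipeline.

The `pca_ols` variant reduces training features to 250 principal components
(train-mean-centered, unscaled — activations are on a common scale and
rescaling would inflate low-variance channels) and fits per-vertex OLS.
The `ridge` variant uses full features with per-vertex penalties selected
by 5-fold cross-validation over λ ∈ 10^(−2…5) (8 log steps) — a
conventional grid; the exact grid is configurable and not asserted.
Evaluation correlates predicted with recorded trial-averaged responses per
vertex, zeroes negative correlations before squaring, and divides by the
test split's own noise-ceiling fraction. Normalized scores can exceed 1 by
estimation noise; they are reported unclipped (a clipping option exists)
because clipping would bias averages of near-ceiling vertices downward.
Model comparisons average per-vertex differences over participants passing
the noise-ceiling rule under both test splits and use a one-sided paired
t-test over participant means.

## OOD machinery

MDS is classical (Torgerson) by default — deterministic, and exact for
configurations that are genuinely low-dimensional; a seeded SMACOF
refinement is available. Only inter-point distances are contractual, as the
embedding is defined up to rotation/reflection. Distributional distance is
the mean Euclidean distance over all (test item, reference item) pairs,
aggregated within test classes; "distance from the remaining clusters" in
split construction means the mean over the other centroids (a min- or
max-based reading would be dominated by single clusters). Zero-shot
identification correlates each recorded pattern with all candidate
predicted patterns and records the rank of the correct image; the
class-sampling protocol draws 8 candidates per class (64 total) without
replacement, re-drawn over 1000 iterations, the pooled protocol ranks among
all candidates once. Chance mean rank is (N + 1)/2.

Split construction embeds candidate responses in 2-D, k-means-partitions
them into 15 clusters (k-means++ seeding, best of five restarts by
within-cluster sum of squares), designates the cluster whose centroid is
most distant (mean over the other centroids) as the OOD cluster, and takes
its `n_ood` most distant items as the OOD test split. The ID split is drawn
uniformly from the remaining clusters and the train split is their
remainder — so OOD-cluster items beyond `n_ood` belong to *no* split. That
exclusion is deliberate: folding near-OOD items back into training would
contaminate the train distribution the OOD test is defined against, at the
cost of the three splits not partitioning the candidate set exactly.

The distance-performance statistic computes a Spearman ρ per participant
between per-class distances and per-class performance and applies a
one-sample, one-sided t-test to the ρ values. When every participant yields
the same ρ (zero variance, as with perfectly monotone simulated data), the
t statistic degenerates; the implementation reports the limiting p-value
(0 in the tested direction, 1 otherwise) instead of erroring.

## The response simulator

`simulate_responses()` draws a random linear readout per vertex, scales the
standardized signal to a target per-vertex signal SD (equal to the true
NCSNR at unit noise SD), and adds per-session offsets and i.i.d. Gaussian
trial noise. Two OOD constructions are available, matching two distinct
uses:

* **Rotation** (`ood_rotation`): a class's signal is rotated towards an
  independent off-readout component, `cos(a)·in-model + sin(a)·off-model`.
  This degrades what a trained readout can predict (encoding scores fall
  as the angle grows) while leaving the marginal response distribution
  unchanged — which also means rotation alone cannot move a class away
  from the training cloud in embedding space.
* **Additive shift** (`ood_shift`): a fixed random vertex pattern, scaled
  in units of mean signal SD, displaces the class's response distribution
  off the training manifold. This is the construction that drives
  distributional-distance analyses; its magnitude is monotonically
  recovered by the embedding distance.

Known limitations: noise is i.i.d. Gaussian across trials and vertices —
no spatial correlations between vertices or ROIs, no temporal
autocorrelation, no hemodynamics; session effects are purely additive.
Passing recovery tests on this generator therefore validates estimator
correctness under the assumed model, not robustness to the richer noise of
real recordings.

## Numerical choices and problem sizes

Validation in the test suite runs at deliberately moderate sizes chosen to
keep Monte-Carlo error well below the asserted tolerances: NCSNR recovery
at 284 images × 3 repeats × 100 vertices (median within ±10% of truth over
the range 0.25–2); perfect-model normalized scores averaged over 50 noise
draws (within 0.1 of 1); encoding recovery with 1000 training images
(median held-out r ≥ 0.8 at NCSNR 1); identification nulls over 200
candidate re-draws; split isolation over 100 replicates; and whole-set
determinism checks on a reduced canvas (320 × 168 at 20 px/degree — the
generator is geometry-parametric, so determinism transfers). The spiral
spatial-frequency law is verified numerically by wrap-safe finite
differences of the phase map, sampled where the local period spans at
least ~8 pixels so the finite difference stays below the phase-wrapping
limit.

Degenerate inputs are contracts, not afterthoughts: constant images error
in percentile normalization; all-identical response sets error in MDS;
constant RSMs yield missing RSA scores; zero-variance paired differences
yield `NA` test statistics; a vertex with zero noise and zero signal has
NCSNR 0 by convention.
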