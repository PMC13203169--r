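# shouldermorph

Desk-scale tools for asking how much of the anatomical-versus-reverse implant
decision in shoulder arthroplasty can be recovered from **bone morphology
alone**. The package implements a two-stage CT analysis pipeline and the
statistics used to compare such a model against a blinded panel of human
raters, exercised end-to-end on synthetic shoulder phantoms so that every
stage is testable on one CPU with no external data.

**Who it is for:** researchers in medical image analysis who want a small,
fully inspectable reference implementation of edge-aware 3D segmentation,
multi-task pathology staging and inter-rater agreement analysis — and a
controllable phantom family to probe them with.

## What is inside

* **Phantom generator** — CT-like volumes with a humeral-head ellipsoid and a
  glenoid-like plate, controllable osteophyte grade (protrusion `<3`, `3–7`,
  `>7` mm), joint-space gap (4 / 1.5 / 0 mm), humeroscapular alignment
  (concentric / eccentric), an implant label generated by a stated rule
  (*reverse iff eccentric OR collapsed joint space OR severe osteophytes*),
  and simulated rater panels with per-class sensitivities and a reverse bias.
* **Edge-aware segmentation** — a dual-decoder 3D U-Net whose region loss is
  `L_r = α(1−D) + (1−α)C` (class-weighted soft Dice `D` plus distance-weighted
  cross-entropy `C`) and whose edge loss is `L_e = βC + (1−β)Ĉ` with the
  reverse cross-entropy `Ĉ`; the spatial weighting is `DWM = exp(−EDT)`,
  concentrating both losses on bone contours. Edge-decoder features fuse into
  the region decoder at every level; a pyramidal module aggregates edges
  across scales. The CPU conv-net engine (im2col convolutions over BLAS,
  reverse-mode differentiation, Adam with gradient clipping) is part of the
  package and is finite-difference-checked in the tests.
* **Reconstruction** — watertight bone meshes from label volumes (tetrahedral
  iso-surfacing of the marching-cubes family, binary STL I/O) and automatic
  glenohumeral-region isolation at the closest approach of the two bones.
* **Multi-task classifier** — shared convolutional encoder, non-linear
  projection and four softmax heads (OS 3, JS 3, HSA 2, implant 2) trained
  with class-weighted cross-entropy, `w_c = (1/N_c)/Σ(1/N_i)`.
* **Metrics** — per-class Dice/Jaccard/precision/recall over voxels; accuracy,
  Macro F1 (unweighted mean of class F1) and Weighted F1 (support-weighted).
* **Agreement** — Fleiss' `κ = (Po − Pe)/(1 − Pe)`, per-case vote entropy
  `H = −Σ p_c log2 p_c`, per-rater sensitivity summaries (with a bundled
  ten-surgeon panel table from a published blinded reading study),
  virtual-consensus logistic regression with stratified CV, and exact
  McNemar tests.

## Worked example

```r
library(shouldermorph)

## the bundled blinded ten-surgeon panel: per-rater accuracy and sensitivity
rater_summary(load_surgeon_panel())
#>  id role a_tp r_tp a_fn r_fn a_se r_se accuracy
#>  01  CoD   29   36   21   14 0.58 0.72     0.65
#>  ...
#>  10  Reg   28   40   22   10 0.56 0.80     0.68
#> cohort: accuracy 0.61 (SD 0.06), A SE 0.53, R SE 0.69

## a simulated panel of ten raters reading 30 phantoms
cases <- lapply(1:30, function(i) { set.seed(i)
  generate_phantom(phantom_config(grid_shape = c(24, 24, 24),
    spacing = c(2, 2, 2), os_grade = sample(0:2, 1), js_grade = sample(0:2, 1),
    hsa_grade = sample(0:1, 1), seed = i)) })
profiles <- replicate(10, rater_profile(0.6, 0.75, 0.1), simplify = FALSE)
r <- generate_rater_panel(cases, profiles, seed = 42)

fleiss_kappa(ratings_to_counts(r, 0:1))
#> Fleiss' kappa 0.0661 (Po 0.6319, Pe 0.6058; 30 items, 10 raters)

H <- panel_entropy(r)
c(mean = mean(H), full_agreement = sum(H == 0), max_disagreement = sum(H == 1))
#>  mean 0.714, 3 cases of full agreement, 2 of maximal disagreement

virtual_consensus(r, attr(r, "truth"), folds = 5, seed = 1)$accuracy
#> 0.9333333   # versus 0.867 for the best single rater
```

The cohort line reads: under morphology-only conditions these raters average
61% implant-type accuracy (SD 0.06) with higher sensitivity for reverse
(0.69) than anatomical (0.53) implants, while a near-chance κ of 0.07 for the
simulated low-sensitivity panel shows how little the raters agree with each
other even when a logistic regression over their pooled votes (the virtual
consensus) recovers far more signal than any individual.

Training the networks follows the same pattern — see
`?train_segmentation`, `?train_classifier` and `?run_pipeline`; the
`vignettes/` directory documents the models, losses and the design decisions
behind them.

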