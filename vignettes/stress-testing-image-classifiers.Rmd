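---
title: "Stress-testing image-based diagnostic classifiers"
author: "DermaStress authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stress-testing image-based diagnostic classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DermaStress)
```

## Why stress tests

A binary image classifier for lesion triage (melanoma vs nevus, with
melanoma the positive class throughout) can match expert discrimination on a
curated benchmark and still be unfit for clinical use. Three failure modes
matter beyond the ROC curve:

* **Miscalibration** — the stated confidence does not match the empirical
  accuracy, so downstream selective workflows ("let the model answer only
  when it is sure") inherit a systematic optimism.
* **Out-of-distribution blindness** — a melanoma/nevus model shown an
  actinic or seborrheic keratosis will confidently predict one of the two
  classes it knows.
* **Capture fragility** — predictions that flip between two photographs of
  the same lesion taken seconds apart, or under a rotation, flip, or mild
  brightness/contrast change.

DermaStress packages the corresponding audits as model-agnostic operations
over a `PredictionSet` (per-image class probabilities plus a manifest
linking images to lesions, datasets, splits, diagnoses and an
out-of-distribution flag). Any classifier that can produce a score table or
be wrapped as `function(image) -> probability vector` can be audited.

## Discrimination

`rocWithDeLongCI()` reports AUROC as the Mann–Whitney concordance
probability (ties half) with a confidence interval from DeLong's
structural-components covariance estimator; `auprScore()` uses the
step-wise, non-interpolated precision–recall area. Operating points carry
sensitivity, specificity, the Youden index $J = \mathrm{sens} +
\mathrm{spec} - 1$ and F1. Because human-benchmark comparisons hinge on the
threshold convention, a positive call is always *strict*:
$\hat y = \text{melanoma} \iff p(\text{melanoma}) > t$.

`sensitivityMatchedThreshold()` selects the **largest** threshold whose
sensitivity still reaches a target (e.g. the mean sensitivity of a panel of
dermatologists' management decisions), which also maximizes specificity
among qualifying thresholds. Candidate thresholds are midpoints between
consecutive distinct scores plus sentinels outside the score range, so a
target of 1 yields a threshold below every positive score and a target of 0
may yield one above all scores.

Rater panels enter as `RaterTable`s of biopsy/reassure decisions.
`raterPoints()` derives each rater's operating point from confusion counts;
the aggregate "rater ROC area" uses the single-point polygon construction
$(0,0) \to (\bar{\mathrm{sens}}, \bar{\mathrm{spec}}) \to (1,1)$, i.e.
$(\bar{\mathrm{sens}} + \bar{\mathrm{spec}})/2$, recorded as such in the
output. `compareModelToRaters()` is a two-sided one-sample t-test of the
per-rater metric against the model's scalar; a zero-variance rater sample
short-circuits to an exact comparison (p = 1 on equality) rather than
inventing a 0/0 statistic.

## Calibration

`fitTemperature()` fits the single scalar of temperature scaling by
minimizing the mean negative log-likelihood of $\mathrm{softmax}(z/T)$ on a
validation split, by bounded scalar minimization on $\log T$ over
$T \in [0.05, 20]$ — bounds wide enough for any practical miscalibration
while guaranteeing termination; an at-bound fit is flagged rather than
rejected. Temperature scaling is rank-preserving, so AUROC is provably
untouched (asserted to 1e-12 in the tests). When a third-party score table
carries only probabilities, logits can be reconstructed as
log-probabilities (exact up to the softmax shift, and sufficient for
temperature fitting); this is opt-in and documented as an approximation.

Calibration quality is the $\ell_2$ (RMS) calibration error
$$\mathrm{RMSE} = \sqrt{\textstyle\sum_b m_b\,(\bar c_b - a_b)^2},$$
with records partitioned into equal-mass bins by confidence (default 15,
boundaries at confidence quantiles, tied confidences kept together).
Equal-mass binning was chosen over equal-width because confidence
distributions of sharp classifiers pile up near 1, where equal-width bins
would be almost empty; the bin table is part of the report so any other
scheme can be recomputed from it. The scale is 0–1: 0 iff every bin's mean
confidence equals its accuracy, exactly 1 for a perfectly sharp,
always-wrong set.

`expectedObservedGap()` compares a test set's response-rate accuracy at each
coverage against the validation set's at the *same coverage* (default), the
convention that makes the two curves directly overlayable; a
threshold-matched variant (validation accuracy above the test set's
coverage-defining confidence cutoff) is provided because either reading is
defensible when the forecast is quoted as "expected accuracy".

## Selective prediction

`rraCurve()` ranks records by descending confidence (confidence = maximum
class probability; ties broken stably by image id, recorded in provenance)
and reports accuracy among the top $\lceil c \cdot n\rceil$ records at each
coverage $c$; correctness is argmax-vs-truth, i.e. the 0.5 melanoma
threshold in the binary case. AURRA is the mean of the curve over the full
per-record grid $\{k/n\}$; the trapezoid-rule area is emitted alongside
because the quadrature convention is not universal, and the two differ only
at $O(1/n)$.

The gambler's loss gives a model an explicit rejection output with payoff
$o > 1$:
$$\mathcal{L} = -\log\left(p_{\text{true}} + p_{\text{reject}}/o\right),$$
reducing exactly to cross-entropy when the rejection mass is zero (a 1e-12
oracle-equivalence test). The payoff default (2.2) and the
reciprocal-payoff rejection rule (reject when the rejection mass exceeds
$1/o$) follow the binary-task regime of the approach's original
formulation and are ordinary arguments, since published uses rarely print
them. `rejectionRates()` reports per-group rejection fractions with exact
binomial intervals — the audit that shows whether a model rejects unfamiliar
disease classes more often than familiar ones.

`oodConfidenceAudit()` compares confidence on in-distribution classes
(maximum class probability per true class) against out-of-distribution
classes, where the melanoma-prediction probability is used — the quantity a
deployed melanoma model would actually assert about an unseen disease.
Pairwise two-sided Wilcoxon rank-sum tests (exact when the combined sample
is small and untied) and Tukey boxplot statistics (median, hinges, 1.5 IQR
whiskers) summarize each comparison.

## Robustness

`applyTransform()` implements the four capture-variation families: rotation
about the centre with bilinear interpolation and **reflection padding**
(zero-fill would introduce black corners that are themselves distribution
shift — the padding mode is the one that adds the least artifact), output
shape unchanged; horizontal flip; multiplicative brightness; and contrast
rescaling about the mean luminance, all clipped to [0, 1]. Identities are
exact (rotation 0, double flip, factor 1) and a full revolution in quarter
turns returns to the input within interpolation tolerance, across image
sizes from 8 to 512 px.

The default battery — rotations every 45°, horizontal flip, brightness and
contrast factors 0.8 and 1.2 — spans the four families symmetrically at
magnitudes meant to emulate capture variation, not corruption, and is fully
overridable. `transformSweep()` classifies each lesion into the exhaustive
four-way taxonomy (consistently correct / consistently wrong / correct
original, wrong transformed / wrong original, correct transformed) at a
threshold fixed *before* the sweep, pools the absolute probability changes
$|p_{\text{transformed}} - p_{\text{original}}|$ across all images and
transforms (median and IQR reported), and reports the non-robust fraction
as the share of lesions in the two flip categories.
`replicateConsistency()` applies the same strict-threshold correctness to
lesions photographed more than once, partitioning them into all correct /
all wrong / mixed; single-image lesions are excluded and counted.
`rotationProfile()` traces the melanoma probability over a dense angle grid
(default every 15°) and flags traces that cross the decision threshold.
`testTimeAugmentation()` averages predictions over the original plus
transformed copies; the paired harness recomputes AUROC for both variants
without asserting a direction, since augmentation averaging is not reliably
an improvement.

## The synthetic corpus and toy classifier

Every audit above is exercised end-to-end on procedurally rendered
lesion-like images: an ellipse with an irregular radial border
$r(\theta) = r_0\,(1 + \epsilon\cos 2\theta + a\cos\theta)
(1 + \sum_k b_k \sin(k\theta + \phi_k))$ on a textured skin-toned
background. The class-separation parameter $\delta$ scales the
melanoma-like class's extra asymmetry, border irregularity and pigment
darkness: $\delta = 0$ makes the class-conditional image distributions
identical (any classifier is at chance), $\delta = 5$ makes them nearly
separable. Replicates of a lesion share frozen parameters and differ by
small pose and illumination jitter with configurable magnitudes, so
replicate-consistency behaviour can be tuned from trivially consistent to
frequently flipping. Out-of-distribution classes come from distinct
parametric families (a rough reddish high-frequency-texture patch; a waxy,
sharply demarcated dark plaque). Rendering is fully deterministic given
(seed, config) and images are quantized to 8-bit PNG, so corpora are
byte-identical across runs.

Defaults were fixed once at values a small clinical photography study would
recognize: 20 lesions per class, 1–3 images per lesion, 64×64 px images,
$\delta = 2$, 3% pose and 8% illumination jitter, and no label noise. Test
runs in this package use smaller corpora (4–18 lesions per class at
16–24 px) purely as problem sizes; none of the defaults were derived from
any test outcome.

`generateScoredPredictions()` provides the calibration ground truth: labels
at a stated prevalence, scores from the equal-variance binormal model with
separation $\mu = \sqrt{2}\,\Phi^{-1}(\mathrm{AUROC})$, whose exactly
calibrated log-odds are linear in the score; emitted logits are the
calibrated logits times a known temperature $T^*$, so `fitTemperature()`
must recover $T^*$ — an identity also cross-checked against a no-intercept
logistic regression.

The toy classifier is a multinomial-logistic model over eight fixed
features (channel means, luminance spread, centre–periphery contrast,
left/right and top/bottom asymmetry, mean gradient), trained by BFGS from
zero initialization so training is deterministic and takes seconds on one
CPU. Its asymmetry features are deliberately pose-sensitive; a model that
were exactly rotation-invariant would make the robustness module
untestable. It is explicitly not a stand-in for clinical performance
claims.

**What passing on synthetic data does and does not show.** The corpus
exercises the *bookkeeping and statistics* of the battery — partitions that
must be exhaustive, thresholds that must be strict, areas that must match
oracles. It does not contain hair, rulers, ink markings, glare, focus loss
or skin-tone diversity, so a clean synthetic run says nothing about a real
model's robustness; it says the audit will measure it faithfully.

## Numerical choices and degenerate inputs

* Probability rows must sum to 1 within 1e-9 (validity), 1e-6 at the
  predictor boundary (then renormalized); logits, when present, must
  reproduce the probabilities through softmax within the same tolerance.
* Confidence ties in ranking: stable image-id order, so every curve is
  reproducible; RMSE binning keeps tied confidences in one bin.
* AUROC with a single-class input is a degenerate-input error; a class with
  one record makes the DeLong variance undefined, degrading to a [0, 1]
  interval with a warning.
* Wilcoxon tests use exact distributions for small untied samples (rank-sum:
  combined n ≤ 20; signed-rank: ≤ 25 non-zero differences) and the
  tie-corrected normal approximation, without continuity correction,
  otherwise. All-zero paired differences give p = 1 with a degeneracy flag.
* Zero-variance rater samples short-circuit the t-test; a gambler payoff
  ≤ 1 is rejected as a degenerate game; a zero log argument in the
  gambler's loss is clamped at 1e-12 and flagged.
* Temperature search is bounded ([0.05, 20] on a log scale); hitting a
  bound sets `converged = FALSE` but still reports the constrained optimum.

## Problem sizes

The shipped tests run the whole battery at deliberately small scale: the
DeLong coverage experiment uses 500 simulations at 50 + 50 records; the
calibration recovery uses n = 2000 at four temperatures; the end-to-end
corpus runs use 8–20 lesions per class at 16–24 px with the default
12-transform battery. The full suite completes in well under a minute on a
single CPU; all sizes are stated in the tests themselves and scale up
linearly if heavier evidence is wanted.

## Known limitations

* Binary triage only; the data model carries an ordered class vector, but
  every metric here assumes one designated positive class.
* The rater ROC area is the single-point polygon construction, not an MRMC
  analysis; inter-rater correlation is not modeled.
* Calibration offers temperature scaling only (no Platt/isotonic/focal
  alternatives), and reported RMSE values depend on the binning scheme,
  which is therefore always emitted with the number.
* The image model is RGB photography; DICOM, EXIF handling and adversarial
  perturbations are out of scope.
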