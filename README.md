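# DermaStress

Computational stress tests for image-based diagnostic classifiers, with
binary melanoma-vs-nevus triage as the worked setting. A model that matches
expert discrimination on a curated benchmark can still be unfit for the
clinic; this package measures the failure modes that conventional reporting
misses, for any classifier that can emit a score table or be wrapped as
`function(image) -> probability vector`:

* **Discrimination** — AUROC as the Mann–Whitney concordance probability
  with DeLong confidence intervals, step-wise AUPR, Youden index
  (sens + spec − 1) and F1 at operating points, thresholds matched to a
  human benchmark's sensitivity, and model-vs-rater statistical
  comparisons.
* **Calibration** — temperature scaling fitted on a validation split
  (scalar `T` minimizing NLL of `softmax(logits / T)`; rank-preserving),
  RMS (ℓ2) calibration error over equal-mass confidence bins
  `sqrt(Σ_b m_b (conf̄_b − acc_b)²)`, and expected-vs-observed accuracy
  gaps across coverage.
* **Selective prediction** — response-rate-accuracy (RRA) curves (accuracy
  among the top-confidence fraction vs coverage), AURRA, the gambler's
  loss `−log(p_true + p_reject / o)` with its rejection-rate audit, and
  out-of-distribution confidence audits with Wilcoxon rank-sum tests.
* **Robustness** — rotation / horizontal-flip / brightness / contrast
  sweeps with a four-way per-lesion verdict taxonomy, replicated-image
  consistency (all correct / all wrong / mixed), rotation probability
  traces, and test-time augmentation.
* **Synthetic fixtures** — a deterministic parametric lesion-image
  generator (two in-distribution classes with a tunable separation δ,
  replicated images, OOD classes), a binormal score generator with known
  true temperature, synthetic rater panels, and a seconds-fast toy
  classifier, so the whole battery runs end-to-end with no clinical data.

All prediction containers are S4 (`PredictionSet`, `RaterTable`,
`TemperatureModel`, `TransformSpec`, ...) with validity checks on the
probability simplex, manifest references and duplicate keys.

## Worked example

A synthetic corpus (δ = 4, 12 lesions per class, replicated images, two
OOD keratosis classes) scored by the bundled toy classifier:

```r
library(DermaStress)

cfg <- syntheticConfig(seed = 19, nLesionsPerClass = 12,
                       imagesPerLesion = c(1, 3), delta = 4, imageSize = 32,
                       oodClasses = c("actinic_keratosis",
                                      "seborrheic_keratosis"),
                       nOODPerClass = 6)
man   <- generateImageCorpus(cfg, writeImages = FALSE)
imgs  <- attr(man, "images")
model <- toyClassifier(man[man$split == "train", ], images = imgs)
pred  <- predictorFunction(model)

evalMan <- man[man$split == "test" | man$is_ood, ]
test <- predictImages(pred, evalMan, c("melanoma", "nevus"), images = imgs)

rocWithDeLongCI(test)
#> ROCCurve: AUROC 1.0000  95% CI [1.0000, 1.0000] (DeLong)
op <- sensitivityMatchedThreshold(test, 0.9)
op
#> OperatingPoint: t = 0.4678  sens = 1.000  spec = 1.000  J = 1.000  F1 = 1.000
#>   provenance: matched to target sensitivity 0.9000
rmsCalibrationError(test, numBins = 5)
#> CalibrationReport: RMSE 0.1532 over 5 equal-mass bins
sw <- transformSweep(pred, evalMan, thresholdValue = op,
                     classNames = c("melanoma", "nevus"), images = imgs)
sw$categoryCounts
#>               consistently_correct                 consistently_wrong
#>                                  1                                  0
#> correct_original_wrong_transformed wrong_original_correct_transformed
#>                                  7                                  0
```

Read together: on held-out synthetic images the toy model discriminates
perfectly (AUROC 1.0) and a dermatologist-sensitivity-matched threshold
looks flawless — yet its confidence overstates its accuracy (RMSE 0.153,
on a 0–1 scale where 0 is perfect calibration) and 7 of 8 evaluated
lesions flip from a correct to a wrong call under at least one mild
rotation/flip/brightness/contrast change. That dissociation — clean
headline metrics, failing stress tests — is precisely what the battery is
built to surface. `replicateConsistency()`, `oodConfidenceAudit()` and
`runStressBattery()` (which writes a JSON report plus per-stage CSVs)
continue the same run; see the vignette in `vignettes/` for the full
methods account.

A command-line front end is available as `exec/stress`
(`stress synth | battery | discriminate | calibrate | rra | replicates |
ood`), exiting 0/2/3 for success / configuration error / stage failure.

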