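#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Fit a temperature-scaling calibrator on a validation split
#'
#' Finds the scalar `T` minimizing the mean negative log-likelihood of
#' `softmax(logits / T)` against the true labels, by bounded scalar
#' minimization on `log T` over `T` in \[0.05, 20\]. Temperature scaling is
#' rank-preserving: no record's class ranking changes, so discrimination is
#' untouched. Sets fitted to data whose logits were inflated by a known
#' factor recover that factor.
#'
#' @param validation a [PredictionSet] with logits and both classes present
#'   (in-distribution, original images are used).
#' @return a [TemperatureModel].
#' @export
fitTemperature <- function(validation) {
  v <- inDistribution(validation)
  stopIfNot(!is.null(logits(v)), "fitTemperature requires logits",
            class = "contractError")
  truth <- match(trueLabels(v), classNames(v))
  stopIfNot(length(unique(truth)) >= 2L, "need both classes to fit",
            class = "degenerateInputError")
  z <- logits(v)
  f <- function(logT) meanNLL(z, truth, exp(logT))
  opt <- optimize(f, interval = log(c(0.05, 20)), tol = 1e-8)
  Tfit <- exp(opt$minimum)
  # at-bound fits are flagged, not rejected: T is still the constrained optimum
  converged <- Tfit > 0.05 * 1.0001 && Tfit < 20 * 0.9999
  new("TemperatureModel", temperature = Tfit,
      nllBefore = meanNLL(z, truth, 1),
      nllAfter = min(opt$objective, meanNLL(z, truth, 1)),
      converged = converged)
}

#' Apply a fitted temperature to a prediction set
#'
#' Replaces probabilities by `softmax(logits / T)` (and logits by
#' `logits / T`, keeping the probs/logits invariant). Rank preservation
#' means the AUROC of the set is unchanged.
#'
#' @param set a [PredictionSet] with logits.
#' @param model a [TemperatureModel].
#' @return the recalibrated [PredictionSet].
#' @export
applyTemperature <- function(set, model) {
  stopIfNot(!is.null(logits(set)), "applyTemperature requires logits",
            class = "contractError")
  z <- logits(set) / model@temperature
  predictionSet(imageIds(set), probs = softmaxRows(z), logits = z,
                manifest = manifest(set), classNames = classNames(set),
                positiveClass = positiveClass(set),
                transformId = transformIds(set))
}

#' RMS (l2) calibration error with equal-mass confidence bins
#'
#' Records are partitioned into (near) equal-mass bins by confidence
#' (maximum class probability); bin boundaries fall at confidence quantiles
#' and tied confidences are kept in one bin. The error is
#' `sqrt(sum_b mass_b * (mean_conf_b - accuracy_b)^2)`, in \[0, 1\]: 0 for a
#' set whose every bin's mean confidence equals its empirical accuracy, 1
#' for a perfectly sharp always-wrong set.
#'
#' @param set a non-empty [PredictionSet].
#' @param numBins number of bins (default 15; reduced with a warning when
#'   there are fewer records than bins).
#' @return a [CalibrationReport].
#' @export
rmsCalibrationError <- function(set, numBins = 15) {
  s <- inDistribution(set)
  n <- length(s)
  stopIfNot(n > 0 && numBins >= 1, "need a non-empty set and numBins >= 1",
            class = "argumentError")
  if (numBins > n) {
    warning("fewer records (", n, ") than bins; using ", n, " bins")
    numBins <- n
  }
  conf <- confidence(s)
  correct <- recordCorrect(s)
  ord <- order(conf)
  # equal-count bins over the sorted order, then merge tied-confidence
  # groups that straddle a boundary into the earlier bin
  rawBin <- ceiling(seq_len(n) / n * numBins)
  tieGroup <- match(conf[ord], unique(conf[ord]))
  binOf <- stats::ave(rawBin, tieGroup, FUN = min)
  bins <- lapply(split(seq_len(n), binOf), function(idx) {
    i <- ord[idx]
    data.frame(mass = length(i) / n, mean_confidence = mean(conf[i]),
               accuracy = mean(correct[i]), n = length(i))
  })
  bins <- do.call(rbind, bins); rownames(bins) <- NULL
  rmse <- sqrt(sum(bins$mass * (bins$mean_confidence - bins$accuracy)^2))
  new("CalibrationReport", rmse = rmse, bins = bins,
      nBins = nrow(bins))
}

#' Expected-vs-observed accuracy gap across coverage
#'
#' The expected accuracy at coverage `c` is the validation set's
#' response-rate accuracy at the same coverage; the observed accuracy is the
#' test set's. Their difference (observed minus expected, percentage points
#' when expressed in %) quantifies how optimistic the validation-derived
#' forecast is. A threshold-matched mode instead takes, at each coverage of
#' the test set, the validation accuracy among validation records whose
#' confidence exceeds the test set's coverage-defining confidence threshold.
#'
#' @param test,validation [PredictionSet]s scored by the same calibrated
#'   model.
#' @param coverageGrid coverages in (0, 1\] at which to compare.
#' @param mode `"coverage"` (default) or `"threshold"`.
#' @return data.frame with coverage, expected, observed, difference.
#' @export
expectedObservedGap <- function(test, validation,
                                coverageGrid = seq(0.05, 1, by = 0.05),
                                mode = c("coverage", "threshold")) {
  mode <- match.arg(mode)
  stopIfNot(length(coverageGrid) > 0, "empty coverage grid",
            class = "argumentError")
  tCurve <- rraCurve(test, coverageGrid)
  observed <- tCurve@accuracies
  if (mode == "coverage") {
    expected <- rraCurve(validation, coverageGrid)@accuracies
  } else {
    ts <- inDistribution(test); vs <- inDistribution(validation)
    confT <- sort(confidence(ts), decreasing = TRUE)
    confV <- confidence(vs); corrV <- recordCorrect(vs)
    expected <- vapply(coverageGrid, function(cv) {
      cut <- confT[ceiling(cv * length(confT))]
      keep <- confV >= cut
      if (!any(keep)) NA_real_ else mean(corrV[keep])
    }, numeric(1))
  }
  data.frame(coverage = coverageGrid, expected = expected,
             observed = observed, difference = observed - expected)
}
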