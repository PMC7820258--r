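#' @import methods
#' @importFrom stats optimize qnorm quantile median sd setNames t.test
#'   wilcox.test binom.test rnorm runif rbinom plogis qlogis fivenum
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

PROB_TOL <- 1e-9

#' PredictionSet: per-image class-probability predictions plus their manifest
#'
#' The central container of the toolkit. It holds one row per
#' `(image_id, transform_id)` pair: the predicted class-probability vector
#' (optionally the logits it was derived from), together with the image
#' manifest the predictions refer to (lesion grouping, dataset, split, true
#' diagnosis, out-of-distribution flag). All metrics in the package consume
#' a `PredictionSet` for one (model, dataset, split).
#'
#' @slot imageId character, one entry per prediction record.
#' @slot transformId character; `""` marks a prediction on the original
#'   (untransformed) image, otherwise the canonical id of the
#'   [TransformSpec] the prediction was made under.
#' @slot probs numeric matrix, records x classes, rows on the simplex
#'   (each entry in \[0,1\], rows summing to 1 within 1e-9). Column names
#'   are the class names.
#' @slot logits optional numeric matrix of the same shape; when present,
#'   `softmax(logits)` must reproduce `probs` within 1e-9.
#' @slot manifest data.frame of image metadata (see [readManifest()]).
#' @slot classNames ordered character vector of declared classes.
#' @slot positiveClass the designated positive class (e.g. `"melanoma"`);
#'   must be one of `classNames`. Explicit so that sensitivity/threshold
#'   logic can never silently flip sign.
#'
#' @seealso [readScores()], [confidence()], [positiveProbs()], [trueLabels()]
#' @export
setClass("PredictionSet",
  representation(
    imageId = "character",
    transformId = "character",
    probs = "matrix",
    logits = "matrixOrNULL",
    manifest = "data.frame",
    classNames = "character",
    positiveClass = "character"
  )
)

setValidity("PredictionSet", function(object) {
  msg <- character()
  n <- length(object@imageId)
  k <- length(object@classNames)
  if (k < 2L) msg <- c(msg, "at least two classes are required")
  if (length(object@positiveClass) != 1L ||
      !(object@positiveClass %in% object@classNames))
    msg <- c(msg, "positiveClass must be one of classNames")
  if (length(object@transformId) != n)
    msg <- c(msg, "transformId length must match imageId")
  if (!identical(dim(object@probs), c(n, k)))
    msg <- c(msg, "probs must be records x classes")
  else {
    if (!identical(colnames(object@probs), object@classNames))
      msg <- c(msg, "probs column names must equal classNames")
    if (any(object@probs < -PROB_TOL) || any(object@probs > 1 + PROB_TOL))
      msg <- c(msg, "probs entries must lie in [0, 1]")
    if (n > 0 && any(abs(rowSums(object@probs) - 1) > PROB_TOL))
      msg <- c(msg, "probs rows must sum to 1 within 1e-9")
  }
  if (!is.null(object@logits)) {
    if (!identical(dim(object@logits), dim(object@probs)))
      msg <- c(msg, "logits must have the same shape as probs")
    else if (n > 0 &&
             max(abs(softmaxRows(object@logits) - object@probs)) > 1e-7)
      msg <- c(msg, "softmax(logits) must reproduce probs")
  }
  man <- object@manifest
  needed <- c("image_id", "lesion_id", "dataset_id", "split", "true_label",
              "is_ood")
  missing <- setdiff(needed, names(man))
  if (length(missing))
    msg <- c(msg, paste0("manifest lacks column(s): ",
                         paste(missing, collapse = ", ")))
  else {
    if (anyDuplicated(man$image_id))
      msg <- c(msg, "manifest image_id values must be unique")
    dangling <- setdiff(object@imageId, man$image_id)
    if (length(dangling))
      msg <- c(msg, paste0("record image_id(s) absent from manifest: ",
                           paste(utils::head(dangling, 5), collapse = ", ")))
  }
  if (n > 0 && anyDuplicated(paste(object@imageId, object@transformId,
                                   sep = "\r")))
    msg <- c(msg, "duplicate (image_id, transform_id) pairs")
  if (length(msg)) msg else TRUE
})

#' TemperatureModel: a fitted temperature-scaling calibrator
#'
#' Temperature scaling divides every logit vector by one scalar `T > 0`
#' before the softmax; it is rank-preserving, so discrimination metrics are
#' untouched while confidence is recalibrated.
#'
#' @slot temperature fitted positive scalar T.
#' @slot nllBefore,nllAfter mean negative log-likelihood on the fitting
#'   split before (T = 1) and after fitting; `nllAfter <= nllBefore` up to
#'   numerical tolerance.
#' @slot converged logical; FALSE flags an optimizer that hit its bounds.
#' @export
setClass("TemperatureModel",
  representation(temperature = "numeric", nllBefore = "numeric",
                 nllAfter = "numeric", converged = "logical")
)

setValidity("TemperatureModel", function(object) {
  msg <- character()
  if (length(object@temperature) != 1L || object@temperature <= 0)
    msg <- c(msg, "temperature must be a positive scalar")
  if (object@nllAfter > object@nllBefore + 1e-9)
    msg <- c(msg, "fitted NLL must not exceed the unfitted NLL")
  if (length(msg)) msg else TRUE
})

#' RaterTable: per-rater binary management decisions
#'
#' Human-reader benchmark: each rater decides, per image, whether to act
#' (biopsy, the positive call) or reassure. Decisions reference manifest
#' image ids; each rater decides each image at most once.
#'
#' @slot decisions data.frame with columns `rater_id`, `image_id`,
#'   `decision` (`"biopsy"` or `"reassure"`).
#' @slot raters optional data.frame of rater metadata keyed by `rater_id`
#'   (experience band, setting, ...).
#' @export
setClass("RaterTable",
  representation(decisions = "data.frame", raters = "data.frame")
)

setValidity("RaterTable", function(object) {
  msg <- character()
  d <- object@decisions
  need <- c("rater_id", "image_id", "decision")
  if (!all(need %in% names(d)))
    msg <- c(msg, "decisions needs columns rater_id, image_id, decision")
  else {
    if (!all(d$decision %in% c("biopsy", "reassure")))
      msg <- c(msg, "decision must be 'biopsy' or 'reassure'")
    if (anyDuplicated(paste(d$rater_id, d$image_id, sep = "\r")))
      msg <- c(msg, "each rater may decide each image at most once")
  }
  if (length(msg)) msg else TRUE
})

#' TransformSpec: one declarative image transformation
#'
#' A transformation of the image-capture kind applied at evaluation time:
#' rotation (degrees, about the image centre, reflection padding), horizontal
#' flip, brightness (multiplicative factor), or contrast (linear rescale
#' about the mean luminance by a factor).
#'
#' @slot kind one of `"rotation"`, `"horizontal_flip"`, `"brightness"`,
#'   `"contrast"`.
#' @slot parameter numeric; degrees in \[0, 360) for rotation, factor > 0 for
#'   brightness/contrast, length 0 for flip.
#' @slot transformId canonical string uniquely encoding (kind, parameter).
#' @seealso [transformSpec()], [applyTransform()], [defaultTransformBattery()]
#' @export
setClass("TransformSpec",
  representation(kind = "character", parameter = "numeric",
                 transformId = "character")
)

setValidity("TransformSpec", function(object) {
  msg <- character()
  kinds <- c("rotation", "horizontal_flip", "brightness", "contrast")
  if (length(object@kind) != 1L || !(object@kind %in% kinds))
    msg <- c(msg, paste0("kind must be one of ", paste(kinds, collapse = ", ")))
  else if (object@kind == "rotation") {
    if (length(object@parameter) != 1L || object@parameter < 0 ||
        object@parameter >= 360)
      msg <- c(msg, "rotation parameter must lie in [0, 360) degrees")
  } else if (object@kind == "horizontal_flip") {
    if (length(object@parameter) != 0L)
      msg <- c(msg, "horizontal_flip takes no parameter")
  } else {
    if (length(object@parameter) != 1L || object@parameter <= 0)
      msg <- c(msg, "brightness/contrast factor must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' OperatingPoint: a probability threshold with its confusion-derived metrics
#'
#' A decision threshold on the positive-class probability together with the
#' sensitivity, specificity, Youden index (sens + spec - 1) and F1 score it
#' achieves, and a provenance tag recording how it was chosen (for example
#' matched to the mean rater sensitivity). A positive call is made when the
#' positive-class probability strictly exceeds the threshold.
#'
#' @slot threshold probability in \[0,1\].
#' @slot sensitivity,specificity achieved rates in \[0,1\].
#' @slot youden sensitivity + specificity - 1.
#' @slot f1 harmonic mean of precision and recall for the positive class.
#' @slot provenance free-text tag.
#' @export
setClass("OperatingPoint",
  representation(threshold = "numeric", sensitivity = "numeric",
                 specificity = "numeric", youden = "numeric", f1 = "numeric",
                 provenance = "character")
)

setValidity("OperatingPoint", function(object) {
  msg <- character()
  if (abs(object@youden - (object@sensitivity + object@specificity - 1)) >
      1e-9)
    msg <- c(msg, "youden must equal sensitivity + specificity - 1")
  if (length(msg)) msg else TRUE
})

#' ROCCurve: an ROC curve with AUROC and its DeLong confidence interval
#'
#' @slot thresholds descending thresholds.
#' @slot sensitivities,specificities rates at each threshold.
#' @slot auroc area under the curve (Mann-Whitney concordance, ties half).
#' @slot aurocCI length-2 numeric (low, high), clipped to \[0,1\].
#' @slot level confidence level of the interval.
#' @export
setClass("ROCCurve",
  representation(thresholds = "numeric", sensitivities = "numeric",
                 specificities = "numeric", auroc = "numeric",
                 aurocCI = "numeric", level = "numeric")
)

setValidity("ROCCurve", function(object) {
  msg <- character()
  if (length(object@aurocCI) != 2L)
    msg <- c(msg, "aurocCI must be (low, high)")
  else if (object@auroc < object@aurocCI[1] - 1e-9 ||
           object@auroc > object@aurocCI[2] + 1e-9)
    msg <- c(msg, "aurocCI must contain auroc")
  if (is.unsorted(rev(object@thresholds)))
    msg <- c(msg, "thresholds must be descending")
  if (length(msg)) msg else TRUE
})

#' RRACurve: response-rate-accuracy curve with AURRA
#'
#' Accuracy among the top-confidence fraction of a test set, as a function
#' of coverage (the fraction of the set the model commits to). Records are
#' ranked by descending confidence with stable image-id tie-break;
#' correctness is argmax-vs-true-label (binary: positive-class probability
#' > 0.5).
#'
#' @slot coverages strictly increasing coverages in (0, 1\].
#' @slot accuracies accuracy among the top `ceiling(c * n)` records.
#' @slot aurra mean of accuracy over the full per-record coverage grid.
#' @slot aurraTrapezoid trapezoid-rule area on the unit coverage interval
#'   (alternative quadrature, reported alongside).
#' @slot n number of records ranked.
#' @export
setClass("RRACurve",
  representation(coverages = "numeric", accuracies = "numeric",
                 aurra = "numeric", aurraTrapezoid = "numeric", n = "integer")
)

setValidity("RRACurve", function(object) {
  msg <- character()
  if (length(object@coverages) != length(object@accuracies))
    msg <- c(msg, "coverages and accuracies must align")
  if (any(diff(object@coverages) <= 0))
    msg <- c(msg, "coverages must be strictly increasing")
  if (length(object@aurra) == 1L &&
      (object@aurra < -1e-12 || object@aurra > 1 + 1e-12))
    msg <- c(msg, "aurra must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' CalibrationReport: RMS calibration error with its reliability bins
#'
#' Records are partitioned into (near) equal-mass bins by confidence;
#' `rmse = sqrt(sum_b mass_b * (mean_confidence_b - accuracy_b)^2)`,
#' in \[0,1\], 0 meaning every bin's mean confidence equals its accuracy.
#'
#' @slot rmse the l2 calibration error.
#' @slot bins data.frame with columns `mass`, `mean_confidence`, `accuracy`,
#'   `n`; masses sum to 1.
#' @slot nBins number of bins actually used.
#' @export
setClass("CalibrationReport",
  representation(rmse = "numeric", bins = "data.frame", nBins = "integer")
)

setValidity("CalibrationReport", function(object) {
  msg <- character()
  if (nrow(object@bins) &&
      abs(sum(object@bins$mass) - 1) > 1e-9)
    msg <- c(msg, "bin masses must sum to 1")
  if (object@rmse < -1e-12 || object@rmse > 1 + 1e-12)
    msg <- c(msg, "rmse must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' ToyClassifier: a small deterministic image classifier over fixed features
#'
#' Multinomial-logistic model over hand-crafted image features (channel
#' means, luminance contrast, asymmetry, border irregularity). The
#' `"gambler"` variant carries an extra rejection output trained with the
#' gambler's loss (payoff `o > 1`), giving the model an explicit abstain
#' option; the `"cross_entropy"` variant is the standard classifier.
#'
#' @slot weights coefficient matrix, (features + 1) x outputs.
#' @slot classNames class names, in output order (rejection output, when
#'   present, is the extra final column).
#' @slot loss `"cross_entropy"` or `"gambler"`.
#' @slot payoff gambler payoff `o` (NA for cross-entropy).
#' @slot featureCenter,featureScale standardization parameters frozen at
#'   training time.
#' @export
setClass("ToyClassifier",
  representation(weights = "matrix", classNames = "character",
                 loss = "character", payoff = "numeric",
                 featureCenter = "numeric", featureScale = "numeric")
)

setMethod("show", "PredictionSet", function(object) {
  man <- object@manifest
  cat("PredictionSet:", length(object@imageId), "records,",
      sum(object@transformId == ""), "on original images\n")
  cat("  classes:", paste(object@classNames, collapse = ", "),
      sprintf("(positive: %s)\n", object@positiveClass))
  cat("  manifest:", nrow(man), "images,",
      length(unique(man$lesion_id)), "lesions,",
      sum(man$is_ood), "OOD\n")
  cat("  logits:", if (is.null(object@logits)) "absent" else "present", "\n")
})

setMethod("show", "TemperatureModel", function(object) {
  cat(sprintf("TemperatureModel: T = %.4f (NLL %.4f -> %.4f, %s)\n",
              object@temperature, object@nllBefore, object@nllAfter,
              if (object@converged) "converged" else "NOT converged"))
})

setMethod("show", "TransformSpec", function(object) {
  cat("TransformSpec:", object@transformId, "\n")
})

setMethod("show", "OperatingPoint", function(object) {
  cat(sprintf(
    "OperatingPoint: t = %.4f  sens = %.3f  spec = %.3f  J = %.3f  F1 = %.3f\n",
    object@threshold, object@sensitivity, object@specificity,
    object@youden, object@f1))
  cat("  provenance:", object@provenance, "\n")
})

setMethod("show", "ROCCurve", function(object) {
  cat(sprintf("ROCCurve: AUROC %.4f  %d%% CI [%.4f, %.4f] (DeLong)\n",
              object@auroc, round(100 * object@level),
              object@aurocCI[1], object@aurocCI[2]))
})

setMethod("show", "RRACurve", function(object) {
  cat(sprintf(
    "RRACurve: n = %d, AURRA %.4f (mean) / %.4f (trapezoid), acc@1 = %.4f\n",
    object@n, object@aurra, object@aurraTrapezoid,
    object@accuracies[length(object@accuracies)]))
})

setMethod("show", "CalibrationReport", function(object) {
  cat(sprintf("CalibrationReport: RMSE %.4f over %d equal-mass bins\n",
              object@rmse, object@nBins))
})

setMethod("show", "RaterTable", function(object) {
  cat("RaterTable:", length(unique(object@decisions$rater_id)), "raters,",
      nrow(object@decisions), "decisions\n")
})

setMethod("show", "ToyClassifier", function(object) {
  cat("ToyClassifier:", object@loss, "loss")
  if (object@loss == "gambler") cat(sprintf(" (payoff o = %.2f)", object@payoff))
  cat(";", nrow(object@weights) - 1L, "features ->",
      ncol(object@weights), "outputs\n")
})
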