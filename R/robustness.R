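#' @include AllClasses.R AllGenerics.R utils.R transforms.R
NULL

ROBUST_CATEGORIES <- c("consistently_correct", "consistently_wrong",
                       "correct_original_wrong_transformed",
                       "wrong_original_correct_transformed")
REPLICATE_CATEGORIES <- c("all_correct", "all_wrong", "mixed")

# correctness of one image's call at the strict > threshold
callCorrect <- function(pPos, truthPos, thresholdValue) {
  (pPos > thresholdValue) == truthPos
}

#' Transformation sweep with four-way robustness verdicts
#'
#' Scores every lesion's original image(s) and every transformed copy, and
#' classifies each lesion into exactly one of four categories at the given
#' decision threshold: consistently correct, consistently wrong, correct on
#' the original but wrong on one or more transformed copies, or wrong on
#' the original but correct on one or more transformed copies.
#'
#' @details A lesion's "original" correctness is the conjunction over its
#' original images (all correct / all wrong; lesions mixed on originals are
#' assigned by their first image and flagged in the output). Absolute
#' probability changes `|p_transformed - p_original|` are pooled over all
#' images and transforms; their median and IQR summarize prediction
#' volatility. The non-robust fraction is the share of lesions in the two
#' flip categories.
#'
#' @param predictor predictor satisfying the [predictImages()] contract, or
#'   NULL when `set` is supplied.
#' @param manifest manifest rows to sweep (non-OOD rows are used).
#' @param specs list of [TransformSpec]s (default battery if NULL).
#' @param thresholdValue decision threshold (strict `>` rule) or an
#'   [OperatingPoint].
#' @param classNames,positiveClass class declaration for the predictor.
#' @param images optional named list of preloaded arrays.
#' @param set optionally, a precomputed [PredictionSet] already containing
#'   original and transformed records (bypasses the predictor).
#' @return list with `verdicts` (data.frame: lesion_id, category,
#'   flipping_transforms, max_abs_change, mixed_original), `changes`
#'   (pooled |dp|), `medianChange`, `iqrChange`, `nonRobustFraction`,
#'   `categoryCounts`.
#' @export
transformSweep <- function(predictor = NULL, manifest = NULL, specs = NULL,
                           thresholdValue, classNames = NULL,
                           positiveClass = "melanoma", images = NULL,
                           set = NULL) {
  if (is(thresholdValue, "OperatingPoint"))
    thresholdValue <- threshold(thresholdValue)
  if (is.null(specs)) specs <- defaultTransformBattery()
  stopIfNot(length(specs) > 0, "specs must be non-empty",
            class = "argumentError")
  if (is.null(set)) {
    man <- manifest[!manifest$is_ood, , drop = FALSE]
    set <- predictImages(predictor, man, classNames,
                         positiveClass = positiveClass, specs = specs,
                         images = images)
  }
  sweepVerdicts(set, thresholdValue)
}

# shared verdict logic over a PredictionSet containing original +
# transformed records
sweepVerdicts <- function(set, thresholdValue) {
  s <- set[!isOOD(set)]
  man <- manifest(s)
  lesion <- man$lesion_id[match(imageIds(s), man$image_id)]
  truthPos <- trueLabels(s) == positiveClass(s)
  pPos <- positiveProbs(s)
  tid <- transformIds(s)
  orig <- tid == ""
  verdicts <- list(); changes <- numeric(0)
  skipped <- character(0)
  for (les in unique(lesion)) {
    sel <- lesion == les
    if (!any(sel & orig)) { skipped <- c(skipped, les); next }
    oCorr <- callCorrect(pPos[sel & orig], truthPos[sel & orig][1],
                         thresholdValue)
    mixedOriginal <- length(unique(oCorr)) > 1
    origCorrect <- oCorr[1]
    tSel <- sel & !orig
    tCorr <- callCorrect(pPos[tSel], truthPos[sel][1], thresholdValue)
    # per-image changes vs that image's own original
    imgs <- unique(imageIds(s)[sel])
    dps <- numeric(0); flips <- character(0)
    for (im in imgs) {
      iSel <- imageIds(s) == im
      p0 <- pPos[iSel & orig]
      if (!length(p0)) next
      pt <- pPos[iSel & !orig]
      dps <- c(dps, abs(pt - p0))
      fl <- callCorrect(pt, truthPos[iSel][1], thresholdValue) !=
        callCorrect(p0, truthPos[iSel][1], thresholdValue)
      flips <- c(flips, tid[iSel & !orig][fl])
    }
    changes <- c(changes, dps)
    category <- if (origCorrect && (!length(tCorr) || all(tCorr)))
      "consistently_correct"
    else if (!origCorrect && (!length(tCorr) || all(!tCorr)))
      "consistently_wrong"
    else if (origCorrect) "correct_original_wrong_transformed"
    else "wrong_original_correct_transformed"
    verdicts[[les]] <- data.frame(
      lesion_id = les, category = category,
      flipping_transforms = paste(unique(flips), collapse = ";"),
      max_abs_change = if (length(dps)) max(dps) else 0,
      mixed_original = mixedOriginal)
  }
  if (length(skipped))
    warning("lesion(s) without an original image skipped: ",
            paste(skipped, collapse = ", "))
  v <- do.call(rbind, c(verdicts, list(make.row.names = FALSE)))
  counts <- table(factor(v$category, levels = ROBUST_CATEGORIES))
  list(verdicts = v, changes = changes,
       medianChange = if (length(changes)) median(changes) else NA_real_,
       iqrChange = if (length(changes)) stats::IQR(changes) else NA_real_,
       nonRobustFraction = mean(v$category %in% ROBUST_CATEGORIES[3:4]),
       categoryCounts = counts)
}

#' Melanoma-probability trace across rotations
#'
#' Evaluates the predictor on the image rotated through a grid of angles
#' (default every 15 degrees in \[0, 360)) and flags the image non-robust
#' when the trace crosses the decision threshold — i.e. the predicted class
#' differs between at least two angles.
#'
#' @param predictor predictor per the [predictImages()] contract.
#' @param image H x W x 3 array.
#' @param thresholdValue decision threshold or [OperatingPoint].
#' @param degreesGrid angles in degrees (non-empty).
#' @param positiveIndex index of the positive class in the predictor's
#'   output (default 1).
#' @return data.frame (degrees, prob) with attributes `crossesThreshold`
#'   and `threshold`.
#' @export
rotationProfile <- function(predictor, image, thresholdValue,
                            degreesGrid = seq(0, 345, by = 15),
                            positiveIndex = 1L) {
  stopIfNot(length(degreesGrid) > 0, "empty rotation grid",
            class = "argumentError")
  if (is(thresholdValue, "OperatingPoint"))
    thresholdValue <- threshold(thresholdValue)
  prob <- vapply(degreesGrid, function(a) {
    img <- if (a %% 360 == 0) image else
      applyTransform(image, transformSpec("rotation", a %% 360))
    predictor(img)[positiveIndex]
  }, numeric(1))
  out <- data.frame(degrees = degreesGrid, prob = prob)
  attr(out, "crossesThreshold") <- any(prob > thresholdValue) &&
    any(prob <= thresholdValue)
  attr(out, "threshold") <- thresholdValue
  out
}

#' Replicated-image consistency
#'
#' For lesions photographed more than once in the same setting (replicated
#' images), classifies each lesion by whether the model's calls at the
#' decision threshold are all correct, all wrong, or mixed across its
#' images. Single-image lesions are excluded and counted.
#'
#' @param set a [PredictionSet] (original, in-distribution records used).
#' @param thresholdValue decision threshold (strict `>`) or
#'   [OperatingPoint].
#' @return list with `verdicts` (lesion_id, category, n_images),
#'   `percentages` (per category, of evaluated lesions), `nEvaluated`,
#'   `nSingleImage`.
#' @export
replicateConsistency <- function(set, thresholdValue) {
  if (is(thresholdValue, "OperatingPoint"))
    thresholdValue <- threshold(thresholdValue)
  s <- inDistribution(set)
  man <- manifest(s)
  lesion <- man$lesion_id[match(imageIds(s), man$image_id)]
  truthPos <- trueLabels(s) == positiveClass(s)
  pPos <- positiveProbs(s)
  sizes <- table(lesion)
  multi <- names(sizes)[sizes >= 2]
  if (!length(multi)) {
    warning("no lesions with replicated images")
    return(list(verdicts = data.frame(lesion_id = character(0),
                                      category = character(0),
                                      n_images = integer(0)),
                percentages = setNames(rep(NA_real_, 3),
                                       REPLICATE_CATEGORIES),
                nEvaluated = 0L, nSingleImage = sum(sizes == 1)))
  }
  verdicts <- do.call(rbind, lapply(multi, function(les) {
    sel <- lesion == les
    corr <- callCorrect(pPos[sel], truthPos[sel][1], thresholdValue)
    data.frame(lesion_id = les,
               category = if (all(corr)) "all_correct"
               else if (!any(corr)) "all_wrong" else "mixed",
               n_images = sum(sel))
  }))
  counts <- table(factor(verdicts$category, levels = REPLICATE_CATEGORIES))
  list(verdicts = verdicts,
       percentages = setNames(100 * as.numeric(counts) / length(multi),
                              REPLICATE_CATEGORIES),
       nEvaluated = length(multi), nSingleImage = sum(sizes == 1))
}

#' Test-time augmentation
#'
#' Scores the original image plus each transformed copy and averages the
#' probability vectors; the result is again a distribution. Identity is
#' always included (the untransformed image is scored).
#'
#' @param predictor predictor per the [predictImages()] contract.
#' @param image H x W x 3 array.
#' @param specs non-empty list of [TransformSpec]s.
#' @return averaged probability vector.
#' @export
testTimeAugmentation <- function(predictor, image, specs) {
  stopIfNot(length(specs) > 0, "specs must be non-empty",
            class = "argumentError")
  preds <- rbind(predictor(image),
                 do.call(rbind, lapply(specs, function(sp)
                   predictor(applyTransform(image, sp)))))
  colMeans(preds)
}
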