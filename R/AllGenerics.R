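#' @include AllClasses.R
NULL

#' Accessors for prediction objects
#'
#' `probs()` returns the records-by-classes probability matrix; `logits()`
#' the logit matrix or NULL; `classNames()` the ordered class vector;
#' `positiveClass()` the designated positive class; `confidence()` the
#' per-record maximum class probability; `positiveProbs()` the
#' positive-class probability per record; `trueLabels()` the true diagnosis
#' per record (looked up in the manifest); `isOOD()` the per-record
#' out-of-distribution flag; `imageIds()` / `transformIds()` the record
#' keys; `manifest()` the image manifest.
#'
#' @param object a [PredictionSet].
#' @return See the individual descriptions.
#' @name prediction-accessors
#' @aliases probs logits classNames positiveClass confidence positiveProbs
#'   trueLabels isOOD imageIds transformIds manifest
NULL

#' @rdname prediction-accessors
#' @export
setGeneric("probs", function(object) standardGeneric("probs"))
#' @rdname prediction-accessors
#' @export
setGeneric("logits", function(object) standardGeneric("logits"))
#' @rdname prediction-accessors
#' @export
setGeneric("classNames", function(object) standardGeneric("classNames"))
#' @rdname prediction-accessors
#' @export
setGeneric("positiveClass", function(object) standardGeneric("positiveClass"))
#' @rdname prediction-accessors
#' @export
setGeneric("confidence", function(object) standardGeneric("confidence"))
#' @rdname prediction-accessors
#' @export
setGeneric("positiveProbs", function(object) standardGeneric("positiveProbs"))
#' @rdname prediction-accessors
#' @export
setGeneric("trueLabels", function(object) standardGeneric("trueLabels"))
#' @rdname prediction-accessors
#' @export
setGeneric("isOOD", function(object) standardGeneric("isOOD"))
#' @rdname prediction-accessors
#' @export
setGeneric("imageIds", function(object) standardGeneric("imageIds"))
#' @rdname prediction-accessors
#' @export
setGeneric("transformIds", function(object) standardGeneric("transformIds"))
#' @rdname prediction-accessors
#' @export
setGeneric("manifest", function(object) standardGeneric("manifest"))

#' @rdname prediction-accessors
setMethod("probs", "PredictionSet", function(object) object@probs)
#' @rdname prediction-accessors
setMethod("logits", "PredictionSet", function(object) object@logits)
#' @rdname prediction-accessors
setMethod("classNames", "PredictionSet", function(object) object@classNames)
#' @rdname prediction-accessors
setMethod("positiveClass", "PredictionSet",
          function(object) object@positiveClass)
#' @rdname prediction-accessors
setMethod("confidence", "PredictionSet", function(object) {
  unname(apply(object@probs, 1L, max))
})
#' @rdname prediction-accessors
setMethod("positiveProbs", "PredictionSet", function(object) {
  unname(object@probs[, object@positiveClass])
})
#' @rdname prediction-accessors
setMethod("trueLabels", "PredictionSet", function(object) {
  man <- object@manifest
  man$true_label[match(object@imageId, man$image_id)]
})
#' @rdname prediction-accessors
setMethod("isOOD", "PredictionSet", function(object) {
  man <- object@manifest
  man$is_ood[match(object@imageId, man$image_id)]
})
#' @rdname prediction-accessors
setMethod("imageIds", "PredictionSet", function(object) object@imageId)
#' @rdname prediction-accessors
setMethod("transformIds", "PredictionSet", function(object) object@transformId)
#' @rdname prediction-accessors
setMethod("manifest", "PredictionSet", function(object) object@manifest)

#' @describeIn prediction-accessors number of prediction records.
#' @export
setMethod("length", "PredictionSet", function(x) length(x@imageId))

#' Subset a PredictionSet by record index
#'
#' Keeps the full manifest (it describes the universe of images, not the
#' selection) and subsets records, probabilities and logits in step.
#'
#' @param x a [PredictionSet]; @param i integer or logical index.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "PredictionSet", function(x, i, j, ..., drop = FALSE) {
  new("PredictionSet",
      imageId = x@imageId[i],
      transformId = x@transformId[i],
      probs = x@probs[i, , drop = FALSE],
      logits = if (is.null(x@logits)) NULL else x@logits[i, , drop = FALSE],
      manifest = x@manifest,
      classNames = x@classNames,
      positiveClass = x@positiveClass)
})

#' Operating-point accessors
#'
#' @param object an [OperatingPoint].
#' @name operating-point-accessors
#' @aliases threshold sensitivity specificity youden f1score
NULL

#' @rdname operating-point-accessors
#' @export
setGeneric("threshold", function(object) standardGeneric("threshold"))
#' @rdname operating-point-accessors
#' @export
setGeneric("sensitivity", function(object) standardGeneric("sensitivity"))
#' @rdname operating-point-accessors
#' @export
setGeneric("specificity", function(object) standardGeneric("specificity"))
#' @rdname operating-point-accessors
#' @export
setGeneric("youden", function(object) standardGeneric("youden"))
#' @rdname operating-point-accessors
#' @export
setGeneric("f1score", function(object) standardGeneric("f1score"))

#' @rdname operating-point-accessors
setMethod("threshold", "OperatingPoint", function(object) object@threshold)
#' @rdname operating-point-accessors
setMethod("sensitivity", "OperatingPoint", function(object) object@sensitivity)
#' @rdname operating-point-accessors
setMethod("specificity", "OperatingPoint", function(object) object@specificity)
#' @rdname operating-point-accessors
setMethod("youden", "OperatingPoint", function(object) object@youden)
#' @rdname operating-point-accessors
setMethod("f1score", "OperatingPoint", function(object) object@f1)

#' Curve and report accessors
#'
#' `auroc()` / `aurocCI()` read an [ROCCurve]; `aurra()` reads the
#' mean-over-grid area from an [RRACurve] (the trapezoid variant is in
#' `object@aurraTrapezoid`); `calibrationRMSE()` reads a
#' [CalibrationReport]; `temperature()` reads a [TemperatureModel].
#'
#' @param object the object to read.
#' @name curve-accessors
#' @aliases auroc aurocCI aurra calibrationRMSE temperature
NULL

#' @rdname curve-accessors
#' @export
setGeneric("auroc", function(object) standardGeneric("auroc"))
#' @rdname curve-accessors
#' @export
setGeneric("aurocCI", function(object) standardGeneric("aurocCI"))
#' @rdname curve-accessors
#' @export
setGeneric("aurra", function(object) standardGeneric("aurra"))
#' @rdname curve-accessors
#' @export
setGeneric("calibrationRMSE", function(object)
  standardGeneric("calibrationRMSE"))
#' @rdname curve-accessors
#' @export
setGeneric("temperature", function(object) standardGeneric("temperature"))

#' @rdname curve-accessors
setMethod("auroc", "ROCCurve", function(object) object@auroc)
#' @rdname curve-accessors
setMethod("aurocCI", "ROCCurve", function(object) object@aurocCI)
#' @rdname curve-accessors
setMethod("aurra", "RRACurve", function(object) object@aurra)
#' @rdname curve-accessors
setMethod("calibrationRMSE", "CalibrationReport", function(object) object@rmse)
#' @rdname curve-accessors
setMethod("temperature", "TemperatureModel", function(object)
  object@temperature)
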