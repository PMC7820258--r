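#' @include AllClasses.R AllGenerics.R utils.R discrimination.R calibration.R
#' @include selective.R robustness.R synthetic.R
NULL

#' Assemble a run configuration for the stress battery
#'
#' Flat key-value configuration with recorded defaults; every value ends up
#' in the report's provenance block. Paths may be NULL when the
#' corresponding stage is to be skipped or when in-memory objects are
#' passed to [runStressBattery()] directly.
#'
#' @param manifestPath,scoresPath,validationScoresPath,raterPath input
#'   tables (CSV/JSON).
#' @param outDir report bundle directory.
#' @param classNames,positiveClass class declaration.
#' @param targetSensitivity when non-NULL, the decision threshold is
#'   matched to this sensitivity on the test set; otherwise
#'   `thresholdValue` is used as-is.
#' @param thresholdValue fixed decision threshold (default 0.5).
#' @param numBins RMSE reliability bins; @param coverageGrid RRA coverages
#'   or `"all"`; @param transformBattery list of [TransformSpec]s;
#' @param seed integer seed recorded and used for any stochastic stage.
#' @return config list.
#' @export
stressConfig <- function(manifestPath = NULL, scoresPath = NULL,
                         validationScoresPath = NULL, raterPath = NULL,
                         outDir = "stress_report",
                         classNames = c("melanoma", "nevus"),
                         positiveClass = "melanoma",
                         targetSensitivity = NULL, thresholdValue = 0.5,
                         numBins = 15, coverageGrid = "all",
                         transformBattery = NULL, seed = 1L) {
  list(manifestPath = manifestPath, scoresPath = scoresPath,
       validationScoresPath = validationScoresPath, raterPath = raterPath,
       outDir = outDir, classNames = classNames,
       positiveClass = positiveClass,
       targetSensitivity = targetSensitivity,
       thresholdValue = thresholdValue, numBins = numBins,
       coverageGrid = coverageGrid,
       transformBattery = transformBattery, seed = as.integer(seed))
}

writeStageCSV <- function(df, outDir, name) {
  path <- file.path(outDir, paste0(name, ".csv"))
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full stress battery
#'
#' Executes, in order: discrimination (AUROC with DeLong CI, AUPR,
#' operating point), calibration (RMSE, expected-vs-observed gap when a
#' validation set is given), selective prediction (RRA curve, AURRA),
#' OOD confidence audit (when OOD records are present), replicated-image
#' consistency, transformation sweep (when a predictor and image paths are
#' available), and test-time augmentation comparison. Each stage failure is
#' caught, recorded in the report, and the remaining stages still run; the
#' function then signals via the `ok` field (the CLI maps it to a nonzero
#' exit).
#'
#' @param config from [stressConfig()].
#' @param testSet,validationSet optional in-memory [PredictionSet]s
#'   (override the path-based inputs).
#' @param raters optional [RaterTable]; @param predictor optional predictor
#'   closure for the image-level stages; @param images optional preloaded
#'   arrays.
#' @return report list (also written to `outDir` as JSON + per-stage CSVs).
#' @export
runStressBattery <- function(config, testSet = NULL, validationSet = NULL,
                             raters = NULL, predictor = NULL,
                             images = NULL) {
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  report <- list(provenance = c(
    config[setdiff(names(config), "transformBattery")],
    list(transform_ids = vapply(
      config$transformBattery %||% defaultTransformBattery(),
      function(s) s@transformId, character(1)),
      tie_break = "descending confidence, stable image_id",
      threshold_rule = "positive call iff p(positive) > t (strict)",
      package_version = as.character(utils::packageVersion("DermaStress")))))
  errors <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  man <- stage("inputs", {
    if (!is.null(testSet)) manifest(testSet) else
      readManifest(config$manifestPath, config$classNames)
  })
  test <- stage("inputs", {
    if (!is.null(testSet)) testSet else
      readScores(config$scoresPath, man, config$classNames,
                 config$positiveClass)
  })
  validation <- stage("inputs", {
    if (!is.null(validationSet)) validationSet
    else if (!is.null(config$validationScoresPath))
      readScores(config$validationScoresPath, man, config$classNames,
                 config$positiveClass)
    else NULL
  })
  if (is.null(raters) && !is.null(config$raterPath))
    raters <- stage("inputs", readRaterTable(config$raterPath, man))

  # decision threshold, fixed before any sweep
  op <- stage("threshold", {
    if (!is.null(config$targetSensitivity))
      sensitivityMatchedThreshold(test, config$targetSensitivity)
    else operatingPoint(test, config$thresholdValue, "configured")
  })

  report$discrimination <- stage("discrimination", {
    roc <- rocWithDeLongCI(test)
    out <- data.frame(metric = c("auroc", "auroc_ci_low", "auroc_ci_high",
                                 "aupr", "threshold", "sensitivity",
                                 "specificity", "youden", "f1"),
                      value = c(auroc(roc), aurocCI(roc)[1], aurocCI(roc)[2],
                                auprScore(test), threshold(op),
                                sensitivity(op), specificity(op),
                                youden(op), f1score(op)))
    writeStageCSV(out, config$outDir, "discrimination")
    out
  })

  report$raterComparison <- if (is.null(raters)) "skipped (no rater table)"
  else stage("rater_comparison", {
    rp <- raterPoints(raters, man, config$positiveClass)
    cmp <- rbind(compareModelToRaters(youden(op), rp$points$youden, "youden"),
                 compareModelToRaters(f1score(op), rp$points$f1, "f1"))
    writeStageCSV(rp$points, config$outDir, "rater_points")
    writeStageCSV(cmp, config$outDir, "rater_comparison")
    list(points = rp$points, raterROCArea = rp$rocArea, test = cmp)
  })

  report$calibration <- stage("calibration", {
    rep <- rmsCalibrationError(test, config$numBins)
    writeStageCSV(rep@bins, config$outDir, "calibration_bins")
    out <- list(rmse = calibrationRMSE(rep), nBins = rep@nBins)
    if (!is.null(validation)) {
      gap <- expectedObservedGap(test, validation,
                                 coverageGrid = seq(0.05, 1, by = 0.05))
      writeStageCSV(gap, config$outDir, "expected_observed_gap")
      out$gapAtFull <- gap$difference[nrow(gap)]
      out$maxGap <- gap$difference[which.max(abs(gap$difference))]
    }
    out
  })

  report$selectivePrediction <- stage("selective_prediction", {
    curve <- rraCurve(test, config$coverageGrid)
    writeStageCSV(data.frame(coverage = curve@coverages,
                             accuracy = curve@accuracies),
                  config$outDir, "rra_curve")
    list(aurra = aurra(curve), aurraTrapezoid = curve@aurraTrapezoid,
         accuracyAtFull = curve@accuracies[length(curve@accuracies)])
  })

  report$oodAudit <- stage("ood_audit", {
    if (!any(isOOD(test))) "skipped (no OOD records)" else {
      audit <- oodConfidenceAudit(test, test)
      writeStageCSV(audit$tests, config$outDir, "ood_tests")
      writeStageCSV(audit$summaries, config$outDir, "ood_summaries")
      audit$tests
    }
  })

  report$replicateConsistency <- stage("replicate_consistency", {
    rc <- replicateConsistency(test, op)
    if (nrow(rc$verdicts))
      writeStageCSV(rc$verdicts, config$outDir, "replicate_verdicts")
    list(percentages = as.list(rc$percentages),
         nEvaluated = rc$nEvaluated, nSingleImage = rc$nSingleImage)
  })

  report$transformSweep <- if (is.null(predictor))
    "skipped (no predictor)"
  else stage("transform_sweep", {
    sw <- transformSweep(predictor, man,
                         specs = config$transformBattery,
                         thresholdValue = op,
                         classNames = config$classNames,
                         positiveClass = config$positiveClass,
                         images = images)
    writeStageCSV(sw$verdicts, config$outDir, "robustness_verdicts")
    list(medianChange = sw$medianChange, iqrChange = sw$iqrChange,
         nonRobustFraction = sw$nonRobustFraction,
         categoryCounts = as.list(sw$categoryCounts))
  })

  report$tta <- if (is.null(predictor)) "skipped (no predictor)"
  else stage("tta", {
    manIn <- man[!man$is_ood, , drop = FALSE]
    specs <- config$transformBattery %||% defaultTransformBattery()
    ttaProbs <- t(vapply(seq_len(nrow(manIn)), function(i) {
      img <- if (!is.null(images)) images[[manIn$image_id[i]]] else
        readImageFile(manIn$path[i])
      testTimeAugmentation(predictor, img, specs)
    }, numeric(length(config$classNames))))
    ttaSet <- predictionSet(manIn$image_id, probs = ttaProbs,
                            manifest = man,
                            classNames = config$classNames,
                            positiveClass = config$positiveClass)
    orig <- test[transformIds(test) == "" &
                   imageIds(test) %in% manIn$image_id]
    out <- data.frame(variant = c("original", "tta"),
                      auroc = c(auroc(rocWithDeLongCI(orig)),
                                auroc(rocWithDeLongCI(ttaSet))))
    writeStageCSV(out, config$outDir, "tta_comparison")
    out
  })

  report$errors <- errors
  report$ok <- length(errors) == 0L
  jsonlite::write_json(report, file.path(config$outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
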