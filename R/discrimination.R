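#' @include AllClasses.R AllGenerics.R utils.R
NULL

# positive-class scores / binary truth among original, non-OOD records
binaryScores <- function(set) {
  s <- inDistribution(set)
  list(score = positiveProbs(s),
       truth = trueLabels(s) == positiveClass(s))
}

#' ROC curve with AUROC and DeLong confidence interval
#'
#' AUROC is the Mann-Whitney concordance probability (probability a random
#' positive is scored above a random negative; ties counted half). The
#' confidence interval uses DeLong's structural-components covariance
#' estimator (midranks for ties), clipped to \[0, 1\]. Restricted to
#' original-image, in-distribution records.
#'
#' @param set a [PredictionSet] with both classes present.
#' @param level confidence level in (0, 1); default 0.95.
#' @return an [ROCCurve].
#' @export
rocWithDeLongCI <- function(set, level = 0.95) {
  b <- binaryScores(set)
  stopIfNot(any(b$truth) && any(!b$truth),
            "AUROC undefined: only one class present",
            class = "degenerateInputError")
  r <- pROC::roc(response = b$truth, predictor = b$score,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  # a degenerate [1,1] interval at AUC 1 is handled, not warned about
  ci <- suppressWarnings(as.numeric(
    pROC::ci.auc(r, conf.level = level, method = "delong")))
  if (anyNA(ci)) {
    # DeLong variance is undefined with a single member of either class;
    # report the maximally uninformative interval rather than NA
    warning("DeLong variance undefined (a class has a single record); ",
            "reporting the [0, 1] interval")
    ci <- c(0, as.numeric(r$auc), 1)
  }
  ord <- order(r$thresholds, decreasing = TRUE)
  new("ROCCurve",
      thresholds = r$thresholds[ord],
      sensitivities = r$sensitivities[ord],
      specificities = r$specificities[ord],
      auroc = as.numeric(r$auc),
      aurocCI = pmin(pmax(ci[c(1, 3)], 0), 1),
      level = level)
}

#' Area under the precision-recall curve
#'
#' Step-wise (non-interpolated) rule: records are ranked by descending
#' positive-class score (stable image-id tie-break for determinism) and the
#' area is the mean, over positives, of precision at each positive's rank —
#' equivalently the sum of precision x recall-increment steps. Lies in
#' \[prevalence, 1\].
#'
#' @param set a [PredictionSet] with at least one positive.
#' @return scalar AUPR.
#' @export
auprScore <- function(set) {
  s <- inDistribution(set)
  b <- list(score = positiveProbs(s), truth = trueLabels(s) ==
              positiveClass(s))
  stopIfNot(any(b$truth), "AUPR undefined: no positives",
            class = "degenerateInputError")
  ord <- order(-b$score, imageIds(s))
  truth <- b$truth[ord]
  tp <- cumsum(truth)
  precision <- tp / seq_along(truth)
  sum(precision[truth]) / sum(truth)
}

#' Confusion-count metrics at a probability threshold
#'
#' Positive call iff the positive-class probability strictly exceeds the
#' threshold. Returns the full [OperatingPoint] (sensitivity, specificity,
#' Youden index, F1).
#'
#' @param set a [PredictionSet]; @param thresholdValue probability in \[0,1\];
#' @param provenance free-text tag recorded on the point.
#' @return an [OperatingPoint].
#' @export
operatingPoint <- function(set, thresholdValue, provenance = "fixed") {
  b <- binaryScores(set)
  call <- b$score > thresholdValue
  tp <- sum(call & b$truth); fn <- sum(!call & b$truth)
  fp <- sum(call & !b$truth); tn <- sum(!call & !b$truth)
  sens <- if (tp + fn) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp) tp / (tp + fp) else 0
  f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  new("OperatingPoint", threshold = thresholdValue, sensitivity = sens,
      specificity = spec, youden = sens + spec - 1, f1 = f1,
      provenance = provenance)
}

#' Operating point matched to a target sensitivity
#'
#' Returns the largest threshold whose sensitivity (strict `>` rule) is at
#' least the target, matching the convention of choosing a model operating
#' point "comparable to" a human benchmark's sensitivity. Candidate
#' thresholds are midpoints between consecutive unique scores plus points
#' below the minimum and above the maximum, so target 1 yields a threshold
#' strictly below every positive score and target 0 may yield one above all
#' scores (empty recall satisfies a target of 0). Ties in sensitivity are
#' broken toward higher specificity, which the largest-threshold rule
#' already guarantees.
#'
#' @param set a [PredictionSet]; @param targetSensitivity value in \[0, 1\].
#' @return an [OperatingPoint] with provenance recording the target.
#' @export
sensitivityMatchedThreshold <- function(set, targetSensitivity) {
  stopIfNot(targetSensitivity >= 0 && targetSensitivity <= 1,
            "target sensitivity must lie in [0,1]", class = "argumentError")
  b <- binaryScores(set)
  u <- sort(unique(b$score))
  candidates <- c(u[1] - 0.05, (u[-length(u)] + u[-1]) / 2,
                  u[length(u)] + 0.05)
  candidates <- rev(candidates)           # descending: largest first
  pos <- b$score[b$truth]
  for (t in candidates) {
    if (mean(pos > t) >= targetSensitivity - 1e-12) {
      op <- operatingPoint(set, t,
        provenance = sprintf("matched to target sensitivity %.4f",
                             targetSensitivity))
      return(op)
    }
  }
  operatingPoint(set, candidates[length(candidates)],
                 provenance = "target sensitivity fallback")
}

#' Per-rater operating points and the aggregate rater ROC area
#'
#' Sensitivity/specificity per rater from management decisions (biopsy =
#' positive call) against the manifest's true labels, restricted to
#' in-distribution images. Raters with decisions on one class only are
#' excluded with a warning. The aggregate rater ROC area is the area of the
#' polygon (0,0) -> mean rater point -> (1,1) in ROC space, i.e.
#' `(mean sensitivity + mean specificity) / 2` — the standard single-point
#' construction, recorded as such in the output.
#'
#' @param raters a [RaterTable]; @param manifest manifest data.frame;
#' @param positiveClass the positive diagnosis (default `"melanoma"`).
#' @return list with `points` (data.frame rater_id, sensitivity,
#'   specificity, n), `meanPoint`, `rocArea`, `construction`.
#' @export
raterPoints <- function(raters, manifest, positiveClass = "melanoma") {
  d <- raters@decisions
  truth <- manifest$true_label[match(d$image_id, manifest$image_id)] ==
    positiveClass
  ood <- manifest$is_ood[match(d$image_id, manifest$image_id)]
  d <- d[!ood, ]; truth <- truth[!ood]
  out <- lapply(split(seq_len(nrow(d)), d$rater_id), function(idx) {
    tr <- truth[idx]; call <- d$decision[idx] == "biopsy"
    if (!any(tr) || all(tr)) return(NULL)
    tp <- sum(call & tr); fp <- sum(call & !tr); fn <- sum(!call & tr)
    data.frame(rater_id = d$rater_id[idx][1],
               sensitivity = mean(call[tr]),
               specificity = mean(!call[!tr]),
               youden = mean(call[tr]) + mean(!call[!tr]) - 1,
               f1 = if (2 * tp + fp + fn > 0)
                 2 * tp / (2 * tp + fp + fn) else 0,
               n = length(idx))
  })
  dropped <- names(out)[vapply(out, is.null, logical(1))]
  if (length(dropped))
    warning("rater(s) excluded (single-class decisions): ",
            paste(dropped, collapse = ", "))
  pts <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(pts) <- NULL
  meanPoint <- c(sensitivity = mean(pts$sensitivity),
                 specificity = mean(pts$specificity))
  list(points = pts, meanPoint = meanPoint,
       rocArea = unname((meanPoint[1] + meanPoint[2]) / 2),
       construction = "polygon (0,0) -> mean rater point -> (1,1)")
}

#' Compare a model metric against per-rater metrics
#'
#' Two-sided one-sample t-test of the per-rater metric values (Youden index
#' or F1, typically) against the model's scalar value, reporting the mean
#' difference (model minus rater mean) and a significance flag at P < 0.05.
#' A zero-variance rater sample short-circuits the test: the difference is
#' reported exactly and p is 1 when it is zero (degenerate equality),
#' 0 otherwise.
#'
#' @param modelValue the model's scalar metric.
#' @param raterValues numeric vector of per-rater metric values (>= 2).
#' @param metric label recorded in the output.
#' @return data.frame with metric, model value, rater mean, mean difference,
#'   statistic, p_value, significant.
#' @export
compareModelToRaters <- function(modelValue, raterValues,
                                 metric = "youden") {
  stopIfNot(length(raterValues) >= 2L, "need at least two raters",
            class = "insufficientDataError")
  diffMean <- modelValue - mean(raterValues)
  if (sd(raterValues) == 0) {
    p <- if (abs(diffMean) < 1e-12) 1 else 0
    stat <- NA_real_
  } else {
    tt <- t.test(raterValues, mu = modelValue, alternative = "two.sided")
    p <- tt$p.value; stat <- unname(tt$statistic)
  }
  data.frame(metric = metric, model = modelValue,
             rater_mean = mean(raterValues), mean_difference = diffMean,
             statistic = stat, p_value = p, significant = p < 0.05)
}

#' Wilcoxon rank-sum comparison of two AUROC samples
#'
#' For per-replicate AUROC samples (ensemble members, bootstrap replicates):
#' two-sided Wilcoxon rank-sum p-value, exact when the combined sample size
#' is at most 20 and there are no ties, normal approximation with tie and
#' continuity correction otherwise.
#'
#' @param sampleA,sampleB numeric AUROC samples.
#' @return data.frame with statistic (W), p_value, method.
#' @export
compareAUROCs <- function(sampleA, sampleB) {
  stopIfNot(length(sampleA) >= 1L && length(sampleB) >= 1L,
            "empty AUROC sample", class = "insufficientDataError")
  exact <- (length(sampleA) + length(sampleB) <= 20L) &&
    !anyDuplicated(c(sampleA, sampleB))
  wt <- suppressWarnings(
    wilcox.test(sampleA, sampleB, exact = exact, correct = FALSE))
  data.frame(statistic = unname(wt$statistic), p_value = wt$p.value,
             method = if (exact) "exact rank-sum" else
               "normal approximation (tie-corrected)")
}
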