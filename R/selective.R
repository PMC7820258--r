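#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Response-rate-accuracy (RRA) curve
#'
#' Records (original images, in-distribution) are ranked by descending
#' confidence, ties broken stably by image id; the accuracy at coverage `c`
#' is the fraction correct among the first `ceiling(c * n)` records, with
#' correctness defined by the argmax class versus the true label (in the
#' binary case, positive-class probability > 0.5). The full grid is
#' `{k/n : k = 1..n}`; AURRA is the mean of accuracy over that grid, with
#' the trapezoid-rule area reported alongside.
#'
#' @param set a non-empty [PredictionSet].
#' @param coverageGrid numeric coverages in (0, 1\], or `"all"` for the full
#'   per-record grid.
#' @return an [RRACurve].
#' @export
rraCurve <- function(set, coverageGrid = "all") {
  s <- inDistribution(set)
  n <- length(s)
  stopIfNot(n > 0, "empty prediction set", class = "argumentError")
  ord <- order(-confidence(s), imageIds(s))
  correct <- recordCorrect(s)[ord]
  prefixAcc <- cumsum(correct) / seq_len(n)
  fullCov <- seq_len(n) / n
  if (identical(coverageGrid, "all")) {
    cov <- fullCov; acc <- prefixAcc
  } else {
    stopIfNot(is.numeric(coverageGrid) && length(coverageGrid) > 0 &&
                all(coverageGrid > 0 & coverageGrid <= 1),
              "coverages must lie in (0, 1]", class = "argumentError")
    cov <- sort(unique(coverageGrid))
    acc <- prefixAcc[ceiling(cov * n)]
  }
  new("RRACurve", coverages = cov, accuracies = acc,
      aurra = mean(prefixAcc),
      aurraTrapezoid = sum(diff(c(0, fullCov)) *
                             (prefixAcc + c(prefixAcc[1], utils::head(
                               prefixAcc, -1))) / 2),
      n = as.integer(n))
}

#' Accuracy of an RRA curve at one coverage
#'
#' @param curve an [RRACurve]; @param coverage a coverage present in (0,1\].
#' @return accuracy among the top `ceiling(coverage * n)` records.
#' @export
rraAt <- function(curve, coverage) {
  i <- which(abs(curve@coverages - coverage) < 1e-9)
  if (length(i) == 1L) return(curve@accuracies[i])
  # fall back to the step function: last coverage not exceeding the query
  i <- max(which(curve@coverages <= coverage + 1e-9))
  curve@accuracies[i]
}

#' Paired Wilcoxon signed-rank comparison of AURRA samples
#'
#' Two-sided signed-rank test on paired per-replicate AURRA values; exact
#' for at most 25 non-zero differences without ties, normal approximation
#' otherwise. All-zero differences are degenerate: p = 1 with a flag.
#'
#' @param sampleA,sampleB equal-length paired numeric samples (n >= 2).
#' @return data.frame with statistic (V), p_value, method, degenerate.
#' @export
compareAURRA <- function(sampleA, sampleB) {
  stopIfNot(length(sampleA) == length(sampleB) && length(sampleA) >= 2L,
            "paired samples of equal length >= 2 required",
            class = "insufficientDataError")
  d <- sampleA - sampleB
  nz <- d[d != 0]
  if (length(nz) == 0L)
    return(data.frame(statistic = NA_real_, p_value = 1,
                      method = "degenerate (all differences zero)",
                      degenerate = TRUE))
  exact <- length(nz) <= 25L && !anyDuplicated(abs(nz))
  wt <- suppressWarnings(
    wilcox.test(sampleA, sampleB, paired = TRUE, exact = exact,
                correct = FALSE))
  data.frame(statistic = unname(wt$statistic), p_value = wt$p.value,
             method = if (exact) "exact signed-rank" else
               "normal approximation", degenerate = FALSE)
}

#' Gambler's loss
#'
#' For a model with an explicit rejection output and payoff `o > 1`, the
#' per-example loss is `-log(p_true + p_reject / o)`: rejecting shields the
#' model from the full cross-entropy penalty at a cost controlled by the
#' payoff. With zero rejection mass it reduces exactly to cross-entropy.
#' Zero arguments to the log are clamped at 1e-12 (flagged via attribute
#' `clamped`).
#'
#' @param outputs numeric matrix, examples x (classes + 1); the final
#'   column is the rejection mass; rows sum to 1.
#' @param trueIdx integer vector of true-class column indices.
#' @param payoff the payoff `o`, must exceed 1.
#' @return mean loss (scalar) with attribute `clamped`.
#' @export
gamblerLoss <- function(outputs, trueIdx, payoff) {
  stopIfNot(payoff > 1, "payoff o must exceed 1 (degenerate game)",
            class = "argumentError")
  stopIfNot(all(abs(rowSums(outputs) - 1) < 1e-6) &&
              all(outputs >= -1e-9),
            "outputs must be distributions over classes + reject",
            class = "argumentError")
  pTrue <- outputs[cbind(seq_len(nrow(outputs)), trueIdx)]
  pReject <- outputs[, ncol(outputs)]
  arg <- pTrue + pReject / payoff
  clamped <- any(arg < 1e-12)
  loss <- mean(-log(pmax(arg, 1e-12)))
  attr(loss, "clamped") <- clamped
  loss
}

#' Per-group rejection rates with exact binomial confidence intervals
#'
#' Fraction of each group whose rejection mass strictly exceeds the decision
#' threshold. Used to audit whether a gambler-loss model rejects
#' out-of-distribution classes more often than in-distribution ones.
#'
#' @param rejectMass numeric rejection masses per example.
#' @param groups factor/character group label per example (class or OOD
#'   class).
#' @param thresholdValue rejection decision threshold; when NULL, the
#'   reciprocal-payoff rule `1 / payoff` is used.
#' @param payoff the gambler payoff behind the default threshold.
#' @param level confidence level for the exact binomial CI.
#' @return data.frame with group, n, rejected, rate, ci_low, ci_high; empty
#'   groups are omitted with a warning.
#' @export
rejectionRates <- function(rejectMass, groups, thresholdValue = NULL,
                           payoff = 2.2, level = 0.95) {
  if (is.null(thresholdValue)) thresholdValue <- 1 / payoff
  groups <- as.character(groups)
  out <- lapply(split(seq_along(rejectMass), groups), function(idx) {
    k <- sum(rejectMass[idx] > thresholdValue); n <- length(idx)
    ci <- binom.test(k, n, conf.level = level)$conf.int
    data.frame(group = groups[idx][1], n = n, rejected = k, rate = k / n,
               ci_low = ci[1], ci_high = ci[2])
  })
  res <- do.call(rbind, out); rownames(res) <- NULL
  res
}

#' Out-of-distribution confidence audit
#'
#' Compares prediction confidence between in-distribution classes
#' (confidence = maximum class probability on images of each true class)
#' and OOD classes (confidence taken as the positive-class, i.e. melanoma,
#' probability — the convention for reporting what the model would assert
#' about an unseen class). For every (in-distribution class, OOD class)
#' pair: two-sided Wilcoxon rank-sum p, medians/IQRs, and Tukey boxplot
#' statistics (median, hinges, 1.5 IQR whiskers).
#'
#' @param inDist a [PredictionSet] of in-distribution records.
#' @param oodSet a [PredictionSet] whose manifest marks OOD records (their
#'   true labels name the OOD classes).
#' @return list with `tests` (data.frame per pair) and `summaries`
#'   (data.frame of boxplot statistics per group).
#' @export
oodConfidenceAudit <- function(inDist, oodSet) {
  ind <- inDistribution(inDist)
  stopIfNot(length(ind) > 0, "empty in-distribution set",
            class = "argumentError")
  oo <- oodSet[isOOD(oodSet) & transformIds(oodSet) == ""]
  stopIfNot(length(oo) > 0, "empty OOD set", class = "argumentError")
  groupsIn <- split(confidence(ind), trueLabels(ind))
  groupsOOD <- split(positiveProbs(oo), trueLabels(oo))
  tests <- list(); summaries <- list()
  for (g in names(c(groupsIn, groupsOOD))) {
    x <- c(groupsIn, groupsOOD)[[g]]
    bs <- grDevices::boxplot.stats(x)$stats
    summaries[[g]] <- data.frame(
      group = g, n = length(x), median = bs[3], q1 = bs[2], q3 = bs[4],
      whisker_low = bs[1], whisker_high = bs[5],
      ood = g %in% names(groupsOOD))
  }
  for (a in names(groupsIn)) for (b in names(groupsOOD)) {
    wt <- suppressWarnings(wilcox.test(groupsIn[[a]], groupsOOD[[b]],
                                       exact = FALSE))
    wtExact <- if (length(groupsIn[[a]]) + length(groupsOOD[[b]]) <= 20 &&
                   !anyDuplicated(c(groupsIn[[a]], groupsOOD[[b]])))
      suppressWarnings(wilcox.test(groupsIn[[a]], groupsOOD[[b]],
                                   exact = TRUE)) else wt
    tests[[paste(a, b, sep = " vs ")]] <- data.frame(
      in_class = a, ood_class = b,
      median_in = median(groupsIn[[a]]), median_ood = median(groupsOOD[[b]]),
      p_value = wtExact$p.value)
  }
  list(tests = do.call(rbind, c(tests, list(make.row.names = FALSE))),
       summaries = do.call(rbind, c(summaries,
                                    list(make.row.names = FALSE))))
}
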