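#' @include AllClasses.R
NULL

# Row-wise softmax with log-sum-exp stabilization.
softmaxRows <- function(z) {
  m <- apply(z, 1L, max)
  e <- exp(z - m)
  out <- e / rowSums(e)
  colnames(out) <- colnames(z)
  out
}

# Mean negative log-likelihood of the true class under softmax(z / Tval).
meanNLL <- function(z, trueIdx, Tval = 1) {
  zs <- z / Tval
  m <- apply(zs, 1L, max)
  lse <- m + log(rowSums(exp(zs - m)))
  mean(lse - zs[cbind(seq_len(nrow(zs)), trueIdx)])
}

# Predicted class index by argmax; first class wins exact ties (binary:
# positive call iff its probability > 0.5 when the positive class is first,
# but correctness helpers below never depend on class order).
argmaxClass <- function(p) {
  max.col(p, ties.method = "first")
}

# Per-record correctness. With threshold = NULL, argmax vs true label.
# With a numeric threshold t, positive call iff positive-class prob > t
# (strict), the decision rule used throughout the robustness analyses.
recordCorrect <- function(set, threshold = NULL) {
  truth <- trueLabels(set)
  if (is.null(threshold)) {
    pred <- classNames(set)[argmaxClass(probs(set))]
  } else {
    pos <- positiveProbs(set) > threshold
    other <- setdiff(classNames(set), positiveClass(set))[1]
    pred <- ifelse(pos, positiveClass(set), other)
  }
  pred == truth
}

# Records made on original (untransformed) images, non-OOD by default.
inDistribution <- function(set, originalOnly = TRUE) {
  keep <- !isOOD(set)
  if (originalOnly) keep <- keep & transformIds(set) == ""
  set[keep]
}

stopIfNot <- function(cond, ..., class) {
  if (!cond) stop(errorCondition(paste0(...), class = c(class, "error")))
}
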