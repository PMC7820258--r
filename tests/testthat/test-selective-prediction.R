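test_that("RRA curves match independent prefix recounts", {
  # perfect set: flat at 1
  s <- makeSet(seq(0.99, 0.6, length.out = 20), rep(TRUE, 20))
  cv <- rraCurve(s)
  expect_equal(cv@accuracies, rep(1, 20))
  expect_equal(aurra(cv), 1)
  # full coverage accuracy equals overall accuracy, always
  set.seed(17)
  for (i in 1:5) {
    n <- sample(20:120, 1)
    p <- runif(n); truth <- runif(n) < 0.5
    s <- makeSet(p, truth)
    cv <- rraCurve(s)
    expect_equal(cv@accuracies[n], mean((p > 0.5) == truth))
    # independent recount at every coverage
    ids <- manifest(s)$image_id
    for (k in c(1, sample(n, 5), n))
      expect_equal(rraAt(cv, k / n), bruteRRA(p, truth, ids, k))
  }
  expect_error(rraCurve(makeSet(0.7, TRUE)[0]), class = "argumentError")
})

test_that("AURRA equals the mean of prefix accuracies and respects ranking structure", {
  # constant confidence: deterministic stable tie-break by image_id
  p <- rep(0.8, 6); truth <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)
  s <- makeSet(p, truth)
  # tie-break sorts by image id img001..img006, so prefix accuracies are
  # computable by hand
  correct <- truth   # p > 0.5 predicts melanoma; correct where truth TRUE
  expect_equal(aurra(rraCurve(s)), mean(cumsum(correct) / seq_along(correct)))
  # permuting records (same ranking) leaves AURRA unchanged
  set.seed(23)
  p <- runif(50); truth <- runif(50) < 0.5
  s1 <- rraCurve(makeSet(p, truth))
  perm <- sample(50)
  s2 <- rraCurve(makeSet(p[perm], truth[perm],
                         ids = sprintf("img%03d", perm)))
  expect_equal(aurra(s1), aurra(s2))
  # confidence ranking perfectly aligned with correctness:
  # RRA non-increasing, AURRA >= accuracy
  pAligned <- c(seq(0.99, 0.9, length.out = 30),
                seq(0.6, 0.51, length.out = 10))
  truthAligned <- c(rep(TRUE, 30), rep(FALSE, 10))
  cv <- rraCurve(makeSet(pAligned, truthAligned))
  expect_true(all(diff(cv@accuracies) <= 1e-12))
  expect_gte(aurra(cv), cv@accuracies[40])
})

test_that("AURRA comparison uses the exact signed-rank distribution", {
  expect_equal(compareAURRA(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))$p_value,
               0.0625)
  res <- compareAURRA(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$p_value, 1)
  expect_true(res$degenerate)
  expect_error(compareAURRA(1, numeric(0)),
               class = "insufficientDataError")
})

test_that("gambler loss reduces to cross-entropy without rejection", {
  set.seed(29)
  n <- 50
  # random distributions over 2 classes + reject
  raw <- matrix(rexp(n * 3), n)
  out <- raw / rowSums(raw)
  truth <- sample(1:2, n, replace = TRUE)
  # zero rejection: exact cross-entropy to 1e-12
  noRej <- cbind(out[, 1:2] / rowSums(out[, 1:2]), 0)
  expect_equal(as.numeric(gamblerLoss(noRej, truth, 2.2)),
               -mean(log(noRej[cbind(1:n, truth)])), tolerance = 1e-12)
  # direct substitution: p_true = 0, p_reject = 1, o = 2 -> log 2
  expect_equal(as.numeric(gamblerLoss(matrix(c(0, 0, 1), 1), 1L, 2)),
               log(2), tolerance = 1e-12)
  # perfect confident prediction -> 0
  expect_equal(as.numeric(gamblerLoss(matrix(c(1, 0, 0), 1), 1L, 2)), 0)
  expect_error(gamblerLoss(out, truth, 1), class = "argumentError")
  # zero log argument clamps with a flag
  l <- gamblerLoss(matrix(c(0, 1, 0), 1), 1L, 2)
  expect_true(attr(l, "clamped"))
})

test_that("rejection rates are direct counts with exact binomial intervals", {
  mass <- c(0, 0, 0.9, 0.8, 0.2, 0.7)
  groups <- c("mel", "mel", "ood", "ood", "mel", "ood")
  rr <- rejectionRates(mass, groups, 0.5)
  expect_equal(rr$rate[rr$group == "mel"], 0)
  expect_equal(rr$rate[rr$group == "ood"], 1)
  expect_equal(rr$ci_low[rr$group == "ood"],
               binom.test(3, 3)$conf.int[1])
  # threshold 0 with positive masses -> everything rejected
  rr0 <- rejectionRates(c(0.1, 0.2), c("a", "a"), 0)
  expect_equal(rr0$rate, 1)
  # all-zero masses -> all rates 0
  expect_equal(rejectionRates(c(0, 0), c("a", "a"), 0.5)$rate, 0)
  # reciprocal-payoff default threshold: 1/o
  expect_equal(rejectionRates(c(0.5, 0.4), c("a", "a"),
                              payoff = 2.2)$rejected, 1L)
})

test_that("OOD confidence audit computes exact rank-sum p and boxplot stats", {
  # in-dist melanoma/nevus + one OOD class, engineered separation:
  # all OOD melanoma-confidences strictly below in-dist -> exact p = 2/252
  man <- asManifest(data.frame(
    image_id = sprintf("i%02d", 1:15),
    lesion_id = sprintf("i%02d", 1:15),
    dataset_id = "d", split = "test",
    true_label = c(rep("melanoma", 5), rep("nevus", 5),
                   rep("seborrheic_keratosis", 5))), CLS)
  pPos <- c(0.91, 0.92, 0.93, 0.94, 0.95,      # melanoma, conf = p
            0.09, 0.08, 0.07, 0.06, 0.05,      # nevus, conf = 1 - p
            0.51, 0.52, 0.53, 0.54, 0.55)      # OOD: melanoma-prob used
  s <- predictionSet(man$image_id, probs = cbind(pPos, 1 - pPos),
                     manifest = man, classNames = CLS)
  audit <- oodConfidenceAudit(s, s)
  pMel <- audit$tests$p_value[audit$tests$in_class == "melanoma"]
  expect_equal(pMel, 2 / choose(10, 5), tolerance = 1e-12)
  # boxplot convention on {1,2,3,4,100}: hinges 2 and 4, whisker at 4
  bs <- grDevices::boxplot.stats(c(1, 2, 3, 4, 100))$stats
  expect_equal(bs, c(1, 2, 3, 4, 4))
  expect_true(all(c("median", "q1", "q3", "whisker_low", "whisker_high")
                  %in% names(audit$summaries)))
  # identical distributions -> p near 1
  pSame <- c(0.9, 0.8, 0.85, 0.7, 0.75, rep(0.1, 5), 0.9, 0.8, 0.85, 0.7,
             0.75)
  s2 <- predictionSet(man$image_id, probs = cbind(pSame, 1 - pSame),
                      manifest = man, classNames = CLS)
  a2 <- oodConfidenceAudit(s2, s2)
  expect_gt(a2$tests$p_value[a2$tests$in_class == "melanoma"], 0.9)
})
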