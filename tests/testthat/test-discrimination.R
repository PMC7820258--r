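test_that("AUROC matches exhaustive pairwise concordance", {
  # perfect separation and complete ties
  s <- makeSet(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(auroc(rocWithDeLongCI(s)), 1.0)
  s <- makeSet(rep(0.4, 6), rep(c(TRUE, FALSE), 3))
  expect_equal(auroc(rocWithDeLongCI(s)), 0.5)
  # seeded draws vs the brute-force pair count, including ties
  set.seed(101)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    p <- round(runif(n), 2)           # rounding forces some ties
    truth <- runif(n) < 0.4
    if (!any(truth) || all(truth)) next
    expect_equal(auroc(rocWithDeLongCI(makeSet(p, truth))),
                 bruteAUROC(p, truth), tolerance = 1e-12)
  }
  expect_error(rocWithDeLongCI(makeSet(runif(5), rep(TRUE, 5))),
               class = "degenerateInputError")
})

test_that("DeLong interval contains the point estimate and respects level", {
  set.seed(3)
  s <- makeSet(runif(80), runif(80) < 0.5)
  roc95 <- rocWithDeLongCI(s, 0.95)
  roc80 <- rocWithDeLongCI(s, 0.80)
  expect_true(aurocCI(roc95)[1] <= auroc(roc95))
  expect_true(aurocCI(roc95)[2] >= auroc(roc95))
  expect_lt(diff(aurocCI(roc80)), diff(aurocCI(roc95)))
  expect_true(all(aurocCI(roc95) >= 0 & aurocCI(roc95) <= 1))
})

test_that("AUPR follows the step-wise rule", {
  # perfect ranking
  s <- makeSet(c(0.9, 0.8, 0.7, 0.6, 0.55, 0.4, 0.3, 0.2, 0.1, 0.05),
               c(rep(TRUE, 5), rep(FALSE, 5)))
  expect_equal(auprScore(s), 1.0)
  # single positive ranked last of n -> 1/n
  n <- 8
  s <- makeSet(seq(0.9, 0.2, length.out = n),
               c(rep(FALSE, n - 1), TRUE))
  expect_equal(auprScore(s), 1 / n)
  # hand enumeration: pos at ranks 1 and 3 of 4 -> (1/1 + 2/3) / 2
  s <- makeSet(c(0.9, 0.7, 0.5, 0.3), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(auprScore(s), (1 + 2 / 3) / 2)
  # uninformative scores approach prevalence (Monte-Carlo, seeded)
  set.seed(77)
  truth <- runif(4000) < 0.3
  s <- makeSet(runif(4000), truth)
  expect_lt(abs(auprScore(s) - 0.3), 0.05)
  expect_gte(auprScore(s), mean(truth) - 0.02)
  expect_error(auprScore(makeSet(runif(5), rep(FALSE, 5))),
               class = "degenerateInputError")
})

test_that("sensitivity-matched thresholds obey the largest-threshold rule", {
  s <- makeSet(c(0.9, 0.6, 0.3, 0.5, 0.2),
               c(TRUE, TRUE, TRUE, FALSE, FALSE))
  op <- sensitivityMatchedThreshold(s, 0.66)
  expect_gt(threshold(op), 0.5)
  expect_lte(threshold(op), 0.6)
  expect_equal(sensitivity(op), 2 / 3)
  # confusion-count recomputation at that threshold
  expect_equal(specificity(op),
               mean(c(0.5, 0.2) <= threshold(op)))
  # target 1: threshold strictly below the minimum positive score
  expect_lt(threshold(sensitivityMatchedThreshold(s, 1)), 0.3)
  expect_equal(sensitivity(sensitivityMatchedThreshold(s, 1)), 1)
  # target 0: a threshold above every score is acceptable
  op0 <- sensitivityMatchedThreshold(s, 0)
  expect_equal(sensitivity(op0), 0)
  expect_gt(threshold(op0), 0.9)
  # monotonicity: higher target never raises the threshold
  set.seed(5)
  s2 <- makeSet(runif(60), runif(60) < 0.5)
  ts <- vapply(seq(0, 1, by = 0.1), function(tg)
    threshold(sensitivityMatchedThreshold(s2, tg)), numeric(1))
  expect_true(all(diff(ts) <= 1e-12))
})

test_that("operating points satisfy the Youden identity and behave at extremes", {
  set.seed(9)
  # random classifier: Youden near 0 at large n
  s <- makeSet(runif(5000), runif(5000) < 0.5)
  op <- operatingPoint(s, 0.5)
  expect_lt(abs(youden(op)), 0.05)
  expect_equal(youden(op), sensitivity(op) + specificity(op) - 1)
  # perfect classifier: Youden 1
  sPerf <- makeSet(c(rep(0.9, 10), rep(0.1, 10)),
                   c(rep(TRUE, 10), rep(FALSE, 10)))
  expect_equal(youden(operatingPoint(sPerf, 0.5)), 1)
  expect_equal(f1score(operatingPoint(sPerf, 0.5)), 1)
})

test_that("rater points come from confusion counts; aggregate area is the polygon rule", {
  man <- makeManifest(rep(c("melanoma", "nevus"), each = 10))
  # rater who biopsies everything and an oracle rater
  dec <- rbind(
    data.frame(rater_id = "all_biopsy", image_id = man$image_id,
               decision = "biopsy"),
    data.frame(rater_id = "oracle", image_id = man$image_id,
               decision = ifelse(man$true_label == "melanoma",
                                 "biopsy", "reassure")))
  rp <- raterPoints(raterTable(dec, man), man)
  expect_equal(rp$points$sensitivity[rp$points$rater_id == "all_biopsy"], 1)
  expect_equal(rp$points$specificity[rp$points$rater_id == "all_biopsy"], 0)
  expect_equal(rp$points$sensitivity[rp$points$rater_id == "oracle"], 1)
  expect_equal(rp$points$specificity[rp$points$rater_id == "oracle"], 1)
  expect_equal(rp$rocArea, (mean(c(1, 1)) + mean(c(0, 1))) / 2)
  # seeded noisy raters equal a direct confusion-count recount
  rt <- generateRaterTable(man, c(0.8, 0.9), c(0.7, 0.6), seed = 21)
  rp2 <- raterPoints(rt, man)
  for (r in rp2$points$rater_id) {
    d <- rt@decisions[rt@decisions$rater_id == r, ]
    truth <- man$true_label[match(d$image_id, man$image_id)] == "melanoma"
    expect_equal(rp2$points$sensitivity[rp2$points$rater_id == r],
                 mean(d$decision[truth] == "biopsy"))
    expect_equal(rp2$points$specificity[rp2$points$rater_id == r],
                 mean(d$decision[!truth] == "reassure"))
  }
})

test_that("model-vs-rater t-test matches the closed form and handles degeneracy", {
  # symmetric sample: zero difference, p = 1
  res <- compareModelToRaters(0.5, c(0.4, 0.5, 0.6))
  expect_equal(res$mean_difference, 0)
  expect_equal(res$p_value, 1)
  # zero-variance equal sample short-circuits
  res <- compareModelToRaters(0.5, c(0.5, 0.5, 0.5))
  expect_equal(res$p_value, 1)
  expect_equal(res$mean_difference, 0)
  # textbook one-sample t: x = {0.2, 0.3, 0.4} vs mu = 0.6
  x <- c(0.2, 0.3, 0.4)
  tExp <- (mean(x) - 0.6) / (sd(x) / sqrt(3))
  pExp <- 2 * pt(abs(tExp), df = 2, lower.tail = FALSE)
  res <- compareModelToRaters(0.6, x)
  expect_equal(res$statistic, tExp, tolerance = 1e-12)
  expect_equal(res$p_value, pExp, tolerance = 1e-12)
  expect_error(compareModelToRaters(0.5, 0.4),
               class = "insufficientDataError")
})

test_that("AUROC-sample comparison is exact for small n, normal-approximate for large", {
  expect_equal(compareAUROCs(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  expect_equal(compareAUROCs(c(1, 2), c(1, 2))$p_value, 1)
  # large-sample path: manual tie-corrected normal approximation oracle
  set.seed(13)
  a <- round(rnorm(30), 1); b <- round(rnorm(30, 0.3), 1)
  r <- rank(c(a, b))
  n1 <- length(a); n2 <- length(b)
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(a, b))
  sig <- sqrt(n1 * n2 / 12 * ((n1 + n2 + 1) -
    sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))))
  z <- (W - n1 * n2 / 2) / sig
  pOracle <- 2 * pnorm(abs(z), lower.tail = FALSE)
  expect_equal(compareAUROCs(a, b)$p_value, pOracle, tolerance = 1e-6)
})
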