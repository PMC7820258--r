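# Fixture builders and independent oracles shared across the suite.

CLS <- c("melanoma", "nevus")

# manifest with one image per lesion unless lesion ids are given
makeManifest <- function(labels, lesions = NULL, split = "test",
                         ids = NULL) {
  n <- length(labels)
  ids <- ids %||% sprintf("img%03d", seq_len(n))
  asManifest(data.frame(
    image_id = ids,
    lesion_id = lesions %||% ids,
    dataset_id = "fixture", split = split, true_label = labels),
    CLS)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# binary PredictionSet from positive-class probabilities and logical truth
makeSet <- function(pPos, truthPos, lesions = NULL, ids = NULL,
                    logits = FALSE) {
  man <- makeManifest(ifelse(truthPos, "melanoma", "nevus"),
                      lesions = lesions, ids = ids)
  if (logits) {
    z <- cbind(qlogis(pmin(pmax(pPos, 1e-12), 1 - 1e-12)), 0)
    predictionSet(man$image_id, logits = z, manifest = man,
                  classNames = CLS)
  } else {
    predictionSet(man$image_id, probs = cbind(pPos, 1 - pPos),
                  manifest = man, classNames = CLS)
  }
}

# exhaustive pairwise-concordance AUROC (ties count half)
bruteAUROC <- function(score, truthPos) {
  pos <- score[truthPos]; neg <- score[!truthPos]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# independent prefix recount of the RRA value at coverage k/n
bruteRRA <- function(pPos, truthPos, ids, k) {
  conf <- pmax(pPos, 1 - pPos)
  ord <- order(-conf, ids)
  correct <- ((pPos > 0.5) == truthPos)[ord]
  mean(correct[seq_len(k)])
}

# random test predictor: a fixed linear map of mean channel intensities
constantPredictor <- function(p) function(image) c(p, 1 - p)
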