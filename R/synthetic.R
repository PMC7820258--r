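#' @include AllClasses.R AllGenerics.R utils.R transforms.R prediction.R
NULL

#' Configuration for the synthetic lesion corpus
#'
#' The generator emulates the structure of a clinical photography dataset
#' for binary triage: two in-distribution diagnosis classes rendered as
#' parametric "lesions" (ellipse with an irregular border on a textured
#' skin background), class imbalance, replicated images per lesion (small
#' pose/illumination jitter, as when several views are taken in one
#' session), and out-of-distribution classes rendered from distinct
#' parametric families. The class-separation parameter `delta` scales how
#' strongly the melanoma-like class differs in asymmetry, border
#' irregularity and pigment darkness: 0 makes the class-conditional image
#' distributions identical (no classifier can beat chance), 5 makes them
#' nearly separable by simple features.
#'
#' @param seed integer; same (seed, config) gives byte-identical images.
#' @param nLesionsPerClass lesions per in-distribution class.
#' @param imagesPerLesion integer range (min, max) of replicates per lesion.
#' @param imageSize square image side in pixels (default 64).
#' @param delta class-separation parameter, >= 0.
#' @param oodClasses character; OOD families to render (any of
#'   `"actinic_keratosis"`, `"seborrheic_keratosis"`).
#' @param nOODPerClass images per OOD class.
#' @param labelNoise fraction of manifest labels flipped, in \[0, 0.5).
#' @param jitterPose,jitterIllumination replicate jitter magnitudes
#'   (fractional offset / multiplicative illumination half-range).
#' @param assertDistinguishable warn when `delta = 0` (the classes are then
#'   statistically identical and no classifier can beat chance).
#' @return config list (validated).
#' @export
syntheticConfig <- function(seed = 1L, nLesionsPerClass = 20L,
                            imagesPerLesion = c(1L, 3L), imageSize = 64L,
                            delta = 2, oodClasses = character(0),
                            nOODPerClass = 10L, labelNoise = 0,
                            jitterPose = 0.03, jitterIllumination = 0.08,
                            assertDistinguishable = FALSE) {
  if (assertDistinguishable && delta == 0)
    warning("delta = 0: class-conditional image distributions are ",
            "identical; expected AUROC of any classifier is 0.5")
  stopIfNot(nLesionsPerClass > 0 && imageSize >= 8 && delta >= 0 &&
              labelNoise >= 0 && labelNoise < 0.5 &&
              all(imagesPerLesion >= 1) && length(imagesPerLesion) == 2,
            "invalid synthetic config", class = "argumentError")
  list(seed = as.integer(seed), nLesionsPerClass = as.integer(nLesionsPerClass),
       imagesPerLesion = as.integer(imagesPerLesion),
       imageSize = as.integer(imageSize), delta = delta,
       oodClasses = oodClasses, nOODPerClass = as.integer(nOODPerClass),
       labelNoise = labelNoise, jitterPose = jitterPose,
       jitterIllumination = jitterIllumination,
       classNames = c("melanoma", "nevus"))
}

# radial border of a lesion: r(theta) = r0 * (1 + sum_k a_k sin(k theta + phi_k))
lesionRadius <- function(theta, r0, amps, phases) {
  k <- seq_along(amps)
  r0 * (1 + colSums(amps * sin(outer(k, theta) + phases)))
}

# render one lesion image; params is a list frozen per lesion
renderLesion <- function(params, size, poseJitter = c(0, 0, 0),
                         illum = 1) {
  cx <- size * (0.5 + poseJitter[1]); cy <- size * (0.5 + poseJitter[2])
  rot <- params$orientation + poseJitter[3]
  # per-pixel polar coordinates about the (jittered) centre
  px <- matrix(rep(seq_len(size), times = size), size) - cx
  py <- matrix(rep(seq_len(size), each = size), size) - cy
  theta <- atan2(py, px) - rot
  rr <- sqrt(px^2 + py^2)
  # asymmetric, elliptical base radius
  base <- params$r0 * size *
    (1 + params$ellip * cos(2 * theta) + params$asym * cos(theta))
  border <- base * (1 + colSums(params$amps *
    sin(outer(seq_along(params$amps), as.vector(theta)) + params$phases)))
  inside <- rr <= matrix(border, size, size)
  # soft edge over ~1px for stable bilinear behaviour
  edge <- pmin(pmax((matrix(border, size, size) - rr + 0.5), 0), 1)
  img <- array(0, c(size, size, 3))
  for (ch in 1:3) {
    bg <- params$skin[ch] + params$skinTexture[[ch]]
    fg <- params$pigment[ch] + params$pigTexture[[ch]]
    img[, , ch] <- bg * (1 - edge) + fg * edge
  }
  pmin(pmax(img * illum, 0), 1)
}

# frozen per-lesion parameters; class-dependence scaled by delta
drawLesionParams <- function(className, delta, size) {
  mel <- className == "melanoma"
  d <- delta / 5                                  # delta 5 ~ near-separable
  irregular <- if (mel) 0.02 + 0.06 * d else 0.02
  asym <- if (mel) 0.05 + 0.25 * d else 0.05
  dark <- if (mel) 0.45 - 0.25 * d else 0.45
  nharm <- 5L
  skin <- c(0.86, 0.70, 0.58) + runif(3, -0.04, 0.04)
  tex <- lapply(1:3, function(i) matrix(runif(size * size, -0.02, 0.02),
                                        size))
  pig <- dark * c(1, 0.75, 0.6) + runif(3, -0.05, 0.05)
  ptex <- lapply(1:3, function(i) matrix(runif(size * size, -0.03, 0.03),
                                         size))
  list(r0 = runif(1, 0.18, 0.28), ellip = runif(1, 0, 0.15),
       asym = asym * runif(1, 0.7, 1.3),
       amps = irregular * runif(nharm, 0.5, 1.5) / seq_len(nharm),
       phases = runif(nharm, 0, 2 * pi),
       orientation = runif(1, 0, 2 * pi),
       skin = skin, skinTexture = tex, pigment = pig, pigTexture = ptex)
}

# OOD families: distinct parametric looks
drawOODParams <- function(className, size) {
  p <- drawLesionParams("nevus", 0, size)
  if (className == "actinic_keratosis") {
    # rough, reddish, scaly patch: high-frequency texture, faint border
    p$pigment <- c(0.75, 0.45, 0.40) + runif(3, -0.05, 0.05)
    p$pigTexture <- lapply(1:3, function(i)
      matrix(runif(size * size, -0.12, 0.12), size))
    p$amps <- 0.10 * runif(5, 0.5, 1.5) / (1:5)
  } else {                                        # seborrheic_keratosis
    # waxy, sharply demarcated, warty brown plaque
    p$pigment <- c(0.40, 0.28, 0.18) + runif(3, -0.05, 0.05)
    p$ellip <- runif(1, 0.2, 0.35)
    p$pigTexture <- lapply(1:3, function(i) {
      g <- outer(sin(seq_len(size) / 2.5), cos(seq_len(size) / 3.1))
      0.06 * g + matrix(runif(size * size, -0.03, 0.03), size)
    })
  }
  p
}

#' Generate a synthetic lesion-image corpus
#'
#' Renders the corpus described by [syntheticConfig()] to PNG files and
#' returns the manifest. Replicates of one lesion share frozen lesion
#' parameters and differ by small pose (centre offset, rotation) and
#' illumination jitter. Fully deterministic given (seed, config).
#'
#' @param config from [syntheticConfig()].
#' @param dir output directory (created); images under `dir/images/`.
#' @param writeImages set FALSE to skip PNG writing and return arrays in
#'   memory (attribute `images` on the manifest).
#' @return manifest data.frame (with `is_ood`), attribute `images` holding
#'   the named list of arrays when `writeImages = FALSE`.
#' @export
generateImageCorpus <- function(config, dir = tempfile("corpus"),
                                writeImages = TRUE) {
  set.seed(config$seed)
  if (writeImages) dir.create(file.path(dir, "images"), recursive = TRUE,
                              showWarnings = FALSE)
  rows <- list(); arrays <- list()
  emit <- function(id, lesion, split, label, img) {
    path <- file.path("images", paste0(id, ".png"))
    if (writeImages) writeImageFile(img, file.path(dir, path))
    else arrays[[id]] <<- img
    rows[[length(rows) + 1L]] <<- data.frame(
      image_id = id, lesion_id = lesion, dataset_id = "synthetic",
      split = split, true_label = label, path = path)
  }
  splits <- c("train", "validation", "test")
  for (cls in config$classNames) {
    for (j in seq_len(config$nLesionsPerClass)) {
      les <- sprintf("%s_les%03d", substr(cls, 1, 3), j)
      params <- drawLesionParams(cls, config$delta, config$imageSize)
      nImg <- sample(config$imagesPerLesion[1]:config$imagesPerLesion[2], 1)
      split <- splits[1 + (j - 1) %% 3]           # lesion-level split
      label <- cls
      if (config$labelNoise > 0 && runif(1) < config$labelNoise)
        label <- setdiff(config$classNames, cls)
      for (r in seq_len(nImg)) {
        pj <- c(runif(2, -config$jitterPose, config$jitterPose),
                runif(1, 0, 2 * pi) * (r > 1))
        il <- 1 + runif(1, -config$jitterIllumination,
                        config$jitterIllumination) * (r > 1)
        emit(sprintf("%s_img%d", les, r), les, split, label,
             renderLesion(params, config$imageSize, pj, il))
      }
    }
  }
  for (cls in config$oodClasses) {
    for (j in seq_len(config$nOODPerClass)) {
      les <- sprintf("%s_les%03d", substr(cls, 1, 3), j)
      params <- drawOODParams(cls, config$imageSize)
      emit(sprintf("%s_img1", les), les, "test", cls,
           renderLesion(params, config$imageSize))
    }
  }
  man <- asManifest(do.call(rbind, rows), config$classNames,
                    dir = if (writeImages) dir else ".")
  if (!writeImages) attr(man, "images") <- arrays
  man
}

#' Generate a scored PredictionSet with known true temperature
#'
#' Binary labels are drawn at the stated prevalence; scores come from the
#' equal-variance binormal model whose separation is chosen to give the
#' requested AUROC (`mu = sqrt(2) * qnorm(auroc)`). Under that model the
#' exactly calibrated log-odds are linear in the score, so the emitted
#' logits — the calibrated logits multiplied by `trueTemperature` — are
#' miscalibrated by precisely that factor: [fitTemperature()] on the set
#' recovers it. Temperature never changes ranking, so the empirical AUROC
#' is invariant to `trueTemperature`.
#'
#' @param n records; @param trueTemperature T* > 0; @param baseAuroc in
#'   \[0.5, 1); @param prevalence positive-class fraction; @param seed RNG
#'   seed; @param split manifest split label.
#' @return a [PredictionSet] with logits; generation recipe in
#'   `attr(, "recipe")`.
#' @export
generateScoredPredictions <- function(n, trueTemperature = 1,
                                      baseAuroc = 0.85, prevalence = 0.5,
                                      seed = 1L, split = "validation") {
  stopIfNot(trueTemperature > 0 && baseAuroc >= 0.5 && baseAuroc < 1,
            "invalid parameters", class = "argumentError")
  set.seed(seed)
  mu <- sqrt(2) * qnorm(baseAuroc)
  y <- rbinom(n, 1, prevalence)
  s <- rnorm(n, mean = ifelse(y == 1, mu / 2, -mu / 2))
  calibrated <- mu * s + qlogis(prevalence)       # exact posterior log-odds
  z <- cbind(calibrated, 0) * trueTemperature
  ids <- sprintf("syn%05d", seq_len(n))
  man <- asManifest(data.frame(
    image_id = ids, lesion_id = ids, dataset_id = "binormal",
    split = split, true_label = ifelse(y == 1, "melanoma", "nevus")),
    c("melanoma", "nevus"))
  out <- predictionSet(ids, logits = z, manifest = man,
                       classNames = c("melanoma", "nevus"),
                       positiveClass = "melanoma")
  attr(out, "recipe") <- list(n = n, trueTemperature = trueTemperature,
                              baseAuroc = baseAuroc,
                              prevalence = prevalence, seed = seed)
  out
}

#' Hand-crafted image features for the toy classifier
#'
#' Mean channel intensities, luminance spread, centre-vs-periphery
#' contrast, left/right and top/bottom asymmetry of luminance, and a border
#' irregularity proxy (mean absolute luminance gradient). Rotation of 90
#' degrees changes which asymmetry axis is which, so the features are only
#' approximately pose-invariant — deliberately, since the robustness module
#' exists to expose such sensitivity.
#'
#' @param image H x W x 3 array.
#' @return named numeric feature vector.
#' @export
imageFeatures <- function(image) {
  image <- asRGBArray(image)
  lum <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  h <- nrow(lum); w <- ncol(lum)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  rr <- sqrt(outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, `+`))
  centre <- rr <= min(h, w) / 4
  gx <- abs(lum[, -1] - lum[, -w]); gy <- abs(lum[-1, ] - lum[-h, ])
  c(meanR = mean(image[, , 1]), meanG = mean(image[, , 2]),
    meanB = mean(image[, , 3]), sdLum = sd(as.vector(lum)),
    centreContrast = mean(lum[centre]) - mean(lum[!centre]),
    asymLR = mean(lum[, seq_len(floor(w / 2))]) -
      mean(lum[, (w - floor(w / 2) + 1):w]),
    asymTB = mean(lum[seq_len(floor(h / 2)), ]) -
      mean(lum[(h - floor(h / 2) + 1):h, ]),
    gradient = mean(gx) + mean(gy))
}

#' Train the toy classifier
#'
#' A multinomial-logistic model over [imageFeatures()], trained by BFGS
#' from zero initialization (deterministic given the data). The
#' `"cross_entropy"` loss gives a standard two-output classifier; the
#' `"gambler"` loss adds a third rejection output trained with
#' [gamblerLoss()] at payoff `o`. Not a claim of clinical-grade
#' performance: the model exists so the stress battery can run end-to-end
#' on synthetic corpora in seconds.
#'
#' @param manifestTrain manifest rows to train on (both classes required).
#' @param images named list of arrays, or NULL to read from `path`.
#' @param loss `"cross_entropy"` or `"gambler"`.
#' @param payoff gambler payoff o (> 1), default 2.2.
#' @param classNames in-distribution classes.
#' @param lambda ridge penalty on the weights (stabilizes separable fits).
#' @return a [ToyClassifier].
#' @export
toyClassifier <- function(manifestTrain, images = NULL,
                          loss = c("cross_entropy", "gambler"),
                          payoff = 2.2, classNames = c("melanoma", "nevus"),
                          lambda = 1e-2) {
  loss <- match.arg(loss)
  man <- manifestTrain[!manifestTrain$is_ood, , drop = FALSE]
  stopIfNot(length(unique(man$true_label)) >= 2L,
            "training data must contain both classes",
            class = "degenerateInputError")
  X <- t(vapply(seq_len(nrow(man)), function(i) {
    img <- if (!is.null(images)) images[[man$image_id[i]]] else
      readImageFile(man$path[i])
    imageFeatures(img)
  }, numeric(8)))
  ctr <- colMeans(X); scl <- pmax(apply(X, 2, sd), 1e-8)
  Xs <- cbind(1, sweep(sweep(X, 2, ctr), 2, scl, "/"))
  yIdx <- match(man$true_label, classNames)
  nOut <- length(classNames) + (loss == "gambler")
  obj <- function(wvec) {
    W <- matrix(wvec, ncol = nOut)
    P <- softmaxRows(Xs %*% W)
    base <- if (loss == "gambler")
      as.numeric(gamblerLoss(P, yIdx, payoff))
    else -mean(log(pmax(P[cbind(seq_along(yIdx), yIdx)], 1e-12)))
    base + lambda * sum(W[-1, ]^2)
  }
  fit <- stats::optim(rep(0, (ncol(Xs)) * nOut), obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  new("ToyClassifier", weights = matrix(fit$par, ncol = nOut),
      classNames = classNames, loss = loss,
      payoff = if (loss == "gambler") payoff else NA_real_,
      featureCenter = ctr, featureScale = scl)
}

#' Predictor function of a toy classifier
#'
#' Returns a closure satisfying the black-box predictor contract: image in,
#' probability vector over the in-distribution classes out. For a gambler
#' model the rejection mass is renormalized away here; use
#' [gamblerOutputs()] for the full (classes + reject) distribution.
#'
#' @param model a [ToyClassifier].
#' @return function(image) -> probability vector.
#' @export
predictorFunction <- function(model) {
  force(model)
  function(image) {
    p <- toyOutputs(model, image)
    k <- length(model@classNames)
    p[seq_len(k)] / sum(p[seq_len(k)])
  }
}

toyOutputs <- function(model, image) {
  f <- imageFeatures(image)
  x <- c(1, (f - model@featureCenter) / model@featureScale)
  drop(softmaxRows(matrix(x %*% model@weights, 1)))
}

#' Full gambler outputs (classes + rejection mass) for a manifest
#'
#' @param model a gambler-loss [ToyClassifier].
#' @param manifest rows to score; @param images optional preloaded arrays.
#' @return data.frame image_id, one column per class, `reject`.
#' @export
gamblerOutputs <- function(model, manifest, images = NULL) {
  stopIfNot(model@loss == "gambler", "model has no rejection output",
            class = "argumentError")
  out <- t(vapply(seq_len(nrow(manifest)), function(i) {
    img <- if (!is.null(images)) images[[manifest$image_id[i]]] else
      readImageFile(manifest$path[i])
    toyOutputs(model, img)
  }, numeric(length(model@classNames) + 1L)))
  df <- data.frame(image_id = manifest$image_id)
  for (k in seq_along(model@classNames)) df[[model@classNames[k]]] <- out[, k]
  df$reject <- out[, ncol(out)]
  df
}

#' Generate a synthetic rater decision table
#'
#' Per rater, a biopsy decision is drawn Bernoulli at the stated
#' sensitivity on truly positive images and `1 - specificity` on truly
#' negative ones, so empirical rates converge to the nominal values with
#' image count. Only in-distribution images are rated.
#'
#' @param manifest truth manifest.
#' @param sensitivities,specificities per-rater rates in \[0,1\] (equal
#'   length; one rater each).
#' @param seed RNG seed; @param positiveClass the positive diagnosis.
#' @return a [RaterTable].
#' @export
generateRaterTable <- function(manifest, sensitivities, specificities,
                               seed = 1L, positiveClass = "melanoma") {
  stopIfNot(length(sensitivities) == length(specificities) &&
              all(c(sensitivities, specificities) >= 0) &&
              all(c(sensitivities, specificities) <= 1),
            "per-rater rates must be in [0,1] and aligned",
            class = "argumentError")
  set.seed(seed)
  man <- manifest[!manifest$is_ood, , drop = FALSE]
  truthPos <- man$true_label == positiveClass
  rows <- lapply(seq_along(sensitivities), function(r) {
    pBiopsy <- ifelse(truthPos, sensitivities[r], 1 - specificities[r])
    data.frame(rater_id = sprintf("rater%02d", r),
               image_id = man$image_id,
               decision = ifelse(runif(nrow(man)) < pBiopsy,
                                 "biopsy", "reassure"))
  })
  raterTable(do.call(rbind, rows), manifest)
}
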