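#' @include AllClasses.R AllGenerics.R utils.R
NULL

MANIFEST_COLS <- c("image_id", "lesion_id", "dataset_id", "split",
                   "true_label")

#' Read and validate an image manifest
#'
#' The manifest links every image to its lesion (replicate-group key),
#' dataset, split and true diagnosis. Out-of-distribution (OOD) flags are
#' derived, never stored: a record is OOD exactly when its `true_label` is
#' outside the declared class set (for a melanoma/nevus model, e.g. actinic
#' or seborrheic keratoses).
#'
#' @param path CSV (header row) or JSON (array of objects) file with columns
#'   `image_id`, `lesion_id`, `dataset_id`, `split`, `true_label` and
#'   optionally `path` (image file location, relative paths resolved against
#'   the manifest's directory).
#' @param classNames ordered character vector of declared classes.
#' @return A validated `data.frame` with the columns above plus `is_ood`.
#' @export
readManifest <- function(path, classNames) {
  stopIfNot(file.exists(path), "manifest file not found: ", path,
            class = "fileError")
  df <- readTable(path)
  missing <- setdiff(MANIFEST_COLS, names(df))
  stopIfNot(length(missing) == 0L,
            "manifest lacks required column(s): ",
            paste(missing, collapse = ", "), class = "schemaError")
  asManifest(df, classNames, dir = dirname(path))
}

#' Build a manifest from an in-memory data.frame
#'
#' @param df data.frame with the manifest columns (see [readManifest()]).
#' @param classNames declared class set; @param dir base dir for relative
#'   image paths.
#' @return validated manifest data.frame with `is_ood` derived.
#' @export
asManifest <- function(df, classNames, dir = ".") {
  dup <- unique(df$image_id[duplicated(df$image_id)])
  stopIfNot(length(dup) == 0L, "duplicate image_id(s): ",
            paste(utils::head(dup, 10), collapse = ", "),
            class = "validationError")
  bad <- setdiff(df$split, c("train", "validation", "test"))
  stopIfNot(length(bad) == 0L, "unknown split value(s): ",
            paste(bad, collapse = ", "), class = "validationError")
  df$is_ood <- !(df$true_label %in% classNames)
  if (!is.null(df$path)) {
    rel <- !is.na(df$path) & nzchar(df$path) &
      !grepl("^(/|[A-Za-z]:)", df$path)
    df$path[rel] <- file.path(dir, df$path[rel])
  }
  rownames(df) <- NULL
  df
}

readTable <- function(path) {
  if (tolower(tools::file_ext(path)) == "json") {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(image_id = "character"))
  }
}

#' Construct a PredictionSet from matrices
#'
#' Low-level constructor used by the readers and generators. When only
#' probabilities are available, logits may be reconstructed as
#' log-probabilities (an approximation up to the softmax shift invariance)
#' via `logitsFromProbs = TRUE`.
#'
#' @param imageId,transformId record keys (`transformId` `""` = original).
#' @param probs records x classes probability matrix (or NULL to derive from
#'   `logits`).
#' @param logits optional logit matrix.
#' @param manifest manifest data.frame (see [asManifest()]).
#' @param classNames,positiveClass declared classes and the positive one.
#' @param logitsFromProbs reconstruct logits as `log(probs)` when absent.
#' @return a [PredictionSet].
#' @export
predictionSet <- function(imageId, probs = NULL, logits = NULL,
                          manifest, classNames,
                          positiveClass = classNames[1],
                          transformId = rep("", length(imageId)),
                          logitsFromProbs = FALSE) {
  if (is.null(probs)) {
    stopIfNot(!is.null(logits), "need probs or logits",
              class = "contractError")
    probs <- softmaxRows(logits)
  }
  colnames(probs) <- classNames
  if (!is.null(logits)) colnames(logits) <- classNames
  if (is.null(logits) && logitsFromProbs)
    logits <- log(pmax(probs, 1e-300))
  new("PredictionSet", imageId = as.character(imageId),
      transformId = as.character(transformId),
      probs = unname(rbind(probs))[, , drop = FALSE] |>
        `colnames<-`(classNames),
      logits = logits, manifest = manifest,
      classNames = classNames, positiveClass = positiveClass)
}

#' Read a score table into a PredictionSet
#'
#' The table has `image_id`, optionally `transform_id` (empty = original),
#' then either `prob_<class>` or `logit_<class>` columns for every declared
#' class. When only logits are given, probabilities are their softmax.
#'
#' @param path CSV or JSON score table.
#' @param manifest manifest data.frame the scores refer to.
#' @param classNames,positiveClass declared classes and the positive one.
#' @param logitsFromProbs when TRUE and the table carries only
#'   probabilities, logits are reconstructed as log-probabilities — an
#'   approximation (softmax is shift-invariant) that nevertheless supports
#'   temperature fitting on third-party score tables.
#' @return a [PredictionSet].
#' @export
readScores <- function(path, manifest, classNames,
                       positiveClass = classNames[1],
                       logitsFromProbs = FALSE) {
  stopIfNot(file.exists(path), "score file not found: ", path,
            class = "fileError")
  df <- readTable(path)
  stopIfNot("image_id" %in% names(df), "score table lacks image_id",
            class = "schemaError")
  unknown <- setdiff(df$image_id, manifest$image_id)
  stopIfNot(length(unknown) == 0L,
            "score image_id(s) absent from manifest: ",
            paste(utils::head(unknown, 10), collapse = ", "),
            class = "referenceError")
  transformId <- if ("transform_id" %in% names(df)) {
    ifelse(is.na(df$transform_id), "", as.character(df$transform_id))
  } else rep("", nrow(df))
  probCols <- paste0("prob_", classNames)
  logitCols <- paste0("logit_", classNames)
  probs <- logits <- NULL
  if (all(probCols %in% names(df))) {
    probs <- as.matrix(df[probCols])
    bad <- abs(rowSums(probs) - 1) > 1e-6
    stopIfNot(!any(bad), "probabilities do not sum to 1 for image_id(s): ",
              paste(utils::head(df$image_id[bad], 10), collapse = ", "),
              class = "validationError")
    probs <- probs / rowSums(probs)   # renormalize within tolerance
  }
  if (all(logitCols %in% names(df)))
    logits <- as.matrix(df[logitCols])
  stopIfNot(!is.null(probs) || !is.null(logits),
            "score table needs prob_<class> or logit_<class> columns",
            class = "schemaError")
  if (!is.null(logits)) probs <- softmaxRows(logits)
  predictionSet(df$image_id, probs = probs, logits = logits,
                manifest = manifest, classNames = classNames,
                positiveClass = positiveClass, transformId = transformId,
                logitsFromProbs = logitsFromProbs)
}

#' Write a manifest / score table
#'
#' CSV serializations matching [readManifest()] / [readScores()]; IDs
#' round-trip exactly and probabilities to better than 1e-9 (15 significant
#' digits).
#'
#' @param manifest manifest data.frame; @param set a [PredictionSet];
#' @param path destination CSV.
#' @name table-writers
NULL

#' @rdname table-writers
#' @export
writeManifest <- function(manifest, path) {
  out <- manifest[setdiff(names(manifest), "is_ood")]
  if (!is.null(out$path)) {
    # store image paths relative to the manifest so the tree is portable
    base <- paste0(normalizePath(dirname(path), mustWork = FALSE), "/")
    abs <- normalizePath(out$path, mustWork = FALSE)
    under <- startsWith(abs, base)
    out$path[under] <- substring(abs[under], nchar(base) + 1L)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname table-writers
#' @export
writeScores <- function(set, path) {
  df <- data.frame(image_id = imageIds(set),
                   transform_id = transformIds(set),
                   stringsAsFactors = FALSE)
  p <- format(probs(set), digits = 15, trim = TRUE, scientific = FALSE)
  for (k in seq_along(classNames(set)))
    df[[paste0("prob_", classNames(set)[k])]] <- p[, k]
  if (!is.null(logits(set))) {
    l <- format(logits(set), digits = 15, trim = TRUE)
    for (k in seq_along(classNames(set)))
      df[[paste0("logit_", classNames(set)[k])]] <- l[, k]
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Average an ensemble of prediction sets
#'
#' Ensemble predictions are the arithmetic mean, per `(image_id,
#' transform_id)` key, of the member probability vectors (the convention for
#' cross-validation ensembles). Members must cover identical key sets and
#' share the class order; logits are dropped (the mean of probabilities has
#' no canonical logit).
#'
#' @param memberSets list of [PredictionSet]s.
#' @return a [PredictionSet] with averaged probabilities.
#' @export
ensembleAverage <- function(memberSets) {
  stopIfNot(length(memberSets) >= 1L, "need at least one member",
            class = "argumentError")
  ref <- memberSets[[1]]
  keyOf <- function(s) paste(imageIds(s), transformIds(s), sep = "\r")
  refKey <- keyOf(ref)
  acc <- matrix(0, length(ref), length(classNames(ref)))
  for (m in memberSets) {
    stopIfNot(identical(classNames(m), classNames(ref)),
              "class order differs between members", class = "alignmentError")
    idx <- match(refKey, keyOf(m))
    missing <- refKey[is.na(idx)]
    extra <- setdiff(keyOf(m), refKey)
    stopIfNot(!anyNA(idx) && length(extra) == 0L,
              "member key sets differ; missing/extra keys: ",
              paste(utils::head(sub("\r.*", "", c(missing, extra)), 10),
                    collapse = ", "),
              class = "alignmentError")
    acc <- acc + probs(m)[idx, , drop = FALSE]
  }
  predictionSet(imageIds(ref), probs = acc / length(memberSets),
                manifest = manifest(ref), classNames = classNames(ref),
                positiveClass = positiveClass(ref),
                transformId = transformIds(ref))
}

#' Score images through a black-box predictor
#'
#' The predictor contract: a function taking an RGB array (height x width x
#' 3, values in \[0,1\]) and returning a probability vector over the declared
#' classes (entries in \[0,1\] summing to 1 within 1e-6). The predictor is
#' invoked exactly once per requested (image, transform) pair, in manifest
#' order then spec order, so output ordering is deterministic.
#'
#' @param predictor the callable described above.
#' @param manifest manifest rows to score (needs a `path` column unless
#'   `images` supplies arrays).
#' @param classNames,positiveClass declared classes and the positive one.
#' @param specs optional list of [TransformSpec]s; each image is also scored
#'   under every spec (the original is always scored).
#' @param images optional named list of preloaded RGB arrays keyed by
#'   image_id (bypasses file reading).
#' @param cacheDir optional directory; when given, every transformed copy
#'   is written there as `<image_id>__<transform_id>.png` for inspection.
#' @return a [PredictionSet].
#' @export
predictImages <- function(predictor, manifest, classNames,
                          positiveClass = classNames[1], specs = list(),
                          images = NULL, cacheDir = NULL) {
  if (!is.null(cacheDir))
    dir.create(cacheDir, recursive = TRUE, showWarnings = FALSE)
  ids <- character(0); tids <- character(0)
  rows <- vector("list", 0L)
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$image_id[i]
    img <- if (!is.null(images)) images[[id]] else
      readImageFile(manifest$path[i])
    for (spec in c(list(NULL), specs)) {
      timg <- if (is.null(spec)) img else applyTransform(img, spec)
      if (!is.null(cacheDir) && !is.null(spec))
        writeImageFile(timg, file.path(cacheDir,
          paste0(id, "__", gsub(":", "-", spec@transformId), ".png")))
      p <- predictor(timg)
      ok <- is.numeric(p) && length(p) == length(classNames) &&
        all(p >= -1e-6 & p <= 1 + 1e-6) && abs(sum(p) - 1) <= 1e-6
      stopIfNot(ok, "predictor output is not a distribution over ",
                length(classNames), " classes for image_id ", id,
                class = "contractError")
      ids <- c(ids, id)
      tids <- c(tids, if (is.null(spec)) "" else spec@transformId)
      rows[[length(rows) + 1L]] <- p / sum(p)
    }
  }
  predictionSet(ids, probs = do.call(rbind, rows), manifest = manifest,
                classNames = classNames, positiveClass = positiveClass,
                transformId = tids)
}

#' Read / write rater decision tables
#'
#' One row per (rater, image) management decision: `"biopsy"` (act; the
#' positive call) or `"reassure"`. Used for human-benchmark operating
#' points.
#'
#' @param path CSV with columns `rater_id`, `image_id`, `decision`, plus any
#'   rater metadata columns (constant within rater) which are split into the
#'   rater table.
#' @param manifest manifest the decisions refer to.
#' @return a [RaterTable].
#' @export
readRaterTable <- function(path, manifest) {
  stopIfNot(file.exists(path), "rater file not found: ", path,
            class = "fileError")
  df <- readTable(path)
  raterTable(df, manifest)
}

#' @rdname readRaterTable
#' @param decisions in-memory decisions data.frame (same schema).
#' @export
raterTable <- function(decisions, manifest) {
  unknown <- setdiff(decisions$image_id, manifest$image_id)
  stopIfNot(length(unknown) == 0L,
            "rater decisions reference unknown image_id(s): ",
            paste(utils::head(unknown, 10), collapse = ", "),
            class = "referenceError")
  meta <- unique(decisions[setdiff(names(decisions),
                                   c("image_id", "decision"))])
  new("RaterTable",
      decisions = decisions[c("rater_id", "image_id", "decision")],
      raters = as.data.frame(meta))
}
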