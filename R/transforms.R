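#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Construct a TransformSpec
#'
#' @param kind `"rotation"`, `"horizontal_flip"`, `"brightness"` or
#'   `"contrast"`.
#' @param parameter degrees in \[0, 360) for rotation, factor > 0 for
#'   brightness/contrast, omitted for flip.
#' @return a [TransformSpec] with a canonical `transformId`
#'   (`"rotation:90"`, `"hflip"`, `"brightness:0.8"`, ...).
#' @export
transformSpec <- function(kind, parameter = numeric(0)) {
  id <- if (kind == "horizontal_flip") "hflip" else
    paste0(kind, ":", format(parameter, trim = TRUE, scientific = FALSE))
  new("TransformSpec", kind = kind, parameter = as.numeric(parameter),
      transformId = id)
}

#' The default transform battery
#'
#' Rotations every 45 degrees (excluding 0), horizontal flip, and mild
#' brightness/contrast factors 0.8 and 1.2 — symmetric, capture-variation
#' magnitudes rather than corruptions. Fully overridable wherever a battery
#' is accepted.
#'
#' @return list of [TransformSpec]s.
#' @export
defaultTransformBattery <- function() {
  c(lapply(seq(45, 315, by = 45), function(a) transformSpec("rotation", a)),
    list(transformSpec("horizontal_flip")),
    lapply(c(0.8, 1.2), function(f) transformSpec("brightness", f)),
    lapply(c(0.8, 1.2), function(f) transformSpec("contrast", f)))
}

# reflect an out-of-range continuous coordinate into [1, n]
# (mirror boundary, period 2n - 2; exact for n >= 2)
reflectIndex <- function(x, n) {
  if (n == 1L) return(rep(1, length(x)))
  p <- 2 * n - 2
  x <- (x - 1) %% p
  ifelse(x > n - 1, p - x, x) + 1
}

#' Apply one image transformation
#'
#' Rotation is about the image centre with bilinear interpolation and
#' reflection padding (mirror boundary, so no artificial black corners),
#' output shape unchanged. Horizontal flip mirrors columns. Brightness
#' multiplies all channels by the factor, clipping to \[0, 1\]. Contrast
#' linearly rescales each channel about the image's mean luminance by the
#' factor, clipping to \[0, 1\].
#'
#' @param image numeric array height x width x 3, values in \[0, 1\] (a
#'   2-D matrix is treated as grayscale and replicated to 3 channels).
#' @param spec a [TransformSpec].
#' @return transformed array of the same shape.
#' @export
applyTransform <- function(image, spec) {
  image <- asRGBArray(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  switch(spec@kind,
    horizontal_flip = image[, w:1, , drop = FALSE],
    brightness = {
      stopIfNot(spec@parameter > 0, "factor must be > 0",
                class = "argumentError")
      pmin(pmax(image * spec@parameter, 0), 1)
    },
    contrast = {
      stopIfNot(spec@parameter > 0, "factor must be > 0",
                class = "argumentError")
      lum <- mean(0.299 * image[, , 1] + 0.587 * image[, , 2] +
                    0.114 * image[, , 3])
      pmin(pmax((image - lum) * spec@parameter + lum, 0), 1)
    },
    rotation = {
      theta <- spec@parameter * pi / 180
      if (theta == 0) return(image)
      cy <- (h + 1) / 2; cx <- (w + 1) / 2
      # inverse map: for each output pixel, sample the source location
      yy <- rep(seq_len(h), times = w) - cy
      xx <- rep(seq_len(w), each = h) - cx
      ct <- cos(theta); st <- sin(theta)
      srcY <- reflectIndex(ct * yy - st * xx + cy, h)
      srcX <- reflectIndex(st * yy + ct * xx + cx, w)
      y0 <- pmin(floor(srcY), h - 1L); x0 <- pmin(floor(srcX), w - 1L)
      y0 <- pmax(y0, 1L); x0 <- pmax(x0, 1L)
      fy <- srcY - y0; fx <- srcX - x0
      out <- array(0, dim(image))
      for (ch in 1:3) {
        m <- image[, , ch]
        v <- (1 - fy) * (1 - fx) * m[cbind(y0, x0)] +
          fy * (1 - fx) * m[cbind(y0 + 1L, x0)] +
          (1 - fy) * fx * m[cbind(y0, x0 + 1L)] +
          fy * fx * m[cbind(y0 + 1L, x0 + 1L)]
        out[, , ch] <- matrix(v, h, w)
      }
      out
    },
    stop("unknown transform kind: ", spec@kind))
}

# coerce to height x width x 3 numeric array in [0,1]
asRGBArray <- function(image) {
  if (is.matrix(image)) image <- array(rep(image, 3), c(dim(image), 3))
  if (length(dim(image)) == 3 && dim(image)[3] == 1)
    image <- array(rep(image, 3), c(dim(image)[1:2], 3))
  if (length(dim(image)) == 3 && dim(image)[3] == 4)
    image <- image[, , 1:3, drop = FALSE]   # drop alpha
  stopIfNot(length(dim(image)) == 3 && dim(image)[3] == 3,
            "image must be an H x W x 3 array", class = "argumentError")
  image
}

#' Read / write image files
#'
#' PNG natively (8-bit RGB; grayscale replicated across channels, alpha
#' dropped); JPEG via EBImage when installed. `writeImageFile()` quantizes
#' to 8 bits so identical arrays always produce byte-identical PNGs.
#'
#' @param path image file path; @param image H x W x 3 array in \[0,1\].
#' @name image-io
NULL

#' @rdname image-io
#' @export
readImageFile <- function(path) {
  stopIfNot(!is.null(path) && !is.na(path) && file.exists(path),
            "image file not found: ", path, class = "fileError")
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("jpg", "jpeg")) {
    stopIfNot(requireNamespace("EBImage", quietly = TRUE),
              "JPEG input requires the EBImage package",
              class = "fileError")
    aperm(asEBArray(EBImage::readImage(path)), c(2, 1, 3))
  } else {
    png::readPNG(path)
  }
  asRGBArray(img)
}

asEBArray <- function(x) {
  a <- EBImage::imageData(x)
  if (length(dim(a)) == 2) array(rep(a, 3), c(dim(a), 3)) else a
}

#' @rdname image-io
#' @export
writeImageFile <- function(image, path) {
  image <- asRGBArray(image)
  png::writePNG(round(pmin(pmax(image, 0), 1) * 255) / 255, path)
  invisible(path)
}
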