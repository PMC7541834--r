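#' Load an image as an RGB array
#'
#' Reads a PNG/JPEG/TIFF raster and returns a `rows x cols x 3` array of
#' reals in \[0, 1\]. Grayscale inputs are replicated into three identical
#' channels; alpha channels are dropped. 8- and 16-bit inputs are scaled by
#' their full range.
#'
#' @param path image file path.
#' @return numeric array `c(rows, cols, 3)` in \[0, 1\].
#' @export
loadImage <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("cannot decode image '", path, "': ",
                                           conditionMessage(e)))
  a <- EBImage::imageData(img)  # dims: (x = col, y = row [, channel])
  if (length(a) == 0L || any(dim(a)[1:2] == 0L)) stop("zero-area image: ", path)
  if (length(dim(a)) == 2L) {
    m <- t(a)
    out <- array(rep(m, 3L), dim = c(nrow(m), ncol(m), 3L))
  } else {
    nch <- dim(a)[3]
    if (nch < 3L) {
      m <- t(a[, , 1L])
      out <- array(rep(m, 3L), dim = c(nrow(m), ncol(m), 3L))
    } else {
      out <- array(0, dim = c(dim(a)[2], dim(a)[1], 3L))
      for (ch in 1:3) out[, , ch] <- t(a[, , ch])
    }
  }
  out[out < 0] <- 0; out[out > 1] <- 1
  out
}

asRGBImage <- function(img) {
  if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  stopifnot(is.array(img), length(dim(img)) == 3L, dim(img)[3] == 3L)
  if (min(img) < 0 || max(img) > 1) stop("RGB values must lie in [0,1]")
  img
}

#' Intensity channel
#'
#' The achromatic channel \eqn{J = (r + g + b)/3}.
#'
#' @param img RGB array in \[0, 1\] (`rows x cols x 3`), or a matrix
#'   (treated as already-gray).
#' @return numeric matrix in \[0, 1\].
#' @export
intensityChannel <- function(img) {
  img <- asRGBImage(img)
  (img[, , 1] + img[, , 2] + img[, , 3]) / 3
}

#' Color opponency channels
#'
#' Computes the four half-wave-rectified opponency maps RG, GR, BY and YB
#' from the tuned color channels
#' \deqn{R = \lfloor r - (g+b)/2 \rfloor,\; G = \lfloor g - (r+b)/2 \rfloor,\;
#'       B = \lfloor b - (r+g)/2 \rfloor,\;
#'       Y = \lfloor (r+g)/2 - |r-g|/2 - b \rfloor}
#' with \eqn{RG = \lfloor R - G \rfloor} etc. Hue is unreliable at low
#' luminance, so all four maps are zeroed where the intensity is at or below
#' `threshold` times its global maximum.
#'
#' @param img RGB array in \[0, 1\].
#' @param threshold low-luminance cutoff as a fraction of the intensity
#'   maximum (default 0.1).
#' @return named list of matrices `RG`, `GR`, `BY`, `YB`.
#' @export
colorOpponencyChannels <- function(img, threshold = 0.1) {
  img <- asRGBImage(img)
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  R <- halfRectify(r - (g + b) / 2)
  G <- halfRectify(g - (r + b) / 2)
  B <- halfRectify(b - (r + g) / 2)
  Y <- halfRectify((r + g) / 2 - abs(r - g) / 2 - b)
  out <- list(
    RG = halfRectify(R - G),
    GR = halfRectify(G - R),
    BY = halfRectify(B - Y),
    YB = halfRectify(Y - B)
  )
  J <- intensityChannel(img)
  dark <- J <= threshold * max(J)
  lapply(out, function(m) { m[dark] <- 0; m })
}

#' Build a half-octave feature pyramid
#'
#' Level 1 is the input map; each subsequent level is downsampled by
#' `scaleFactor` (\eqn{\sqrt 2} by default, so 7 levels span three octaves).
#' Level sizes are computed from level 1 (rounded to nearest integer), not
#' cumulatively, to avoid rounding drift.
#'
#' @param map numeric matrix (finest level).
#' @param nLevels number of levels (default 7).
#' @param channel label stored with the pyramid.
#' @param scaleFactor per-level linear downsampling factor.
#' @return a [FeaturePyramid-class].
#' @export
buildPyramid <- function(map, nLevels = 7L, channel = "J", scaleFactor = sqrt(2)) {
  stopifnot(is.matrix(map), nLevels >= 1L, scaleFactor > 1)
  d1 <- dim(map)
  dmin <- round(d1 / scaleFactor^(nLevels - 1L))
  if (any(dmin < 4L))
    stop(sprintf("input %dx%d too small for %d pyramid levels", d1[1], d1[2], nLevels))
  levels <- vector("list", nLevels)
  levels[[1L]] <- map
  for (k in seq_len(nLevels)[-1L]) {
    dk <- round(d1 / scaleFactor^(k - 1L))
    levels[[k]] <- resizeMap(map, dk[1], dk[2])
  }
  methods::new("FeaturePyramid", levels = levels, channel = channel,
               scaleFactor = scaleFactor)
}

#' Rescale an image to the model's pixels-per-degree
#'
#' The model's filter bank assumes a fixed retinal sampling (about 30 pixels
#' per degree of visual angle or more, given the 4-px Gabor wavelength).
#' Datasets recorded at a different pixels-per-degree are resampled by the
#' factor `modelPpd / datasetPpd` so that stimulus spatial frequencies land
#' on the right filters.
#'
#' @param img RGB array.
#' @param datasetPpd pixels per degree of the recording setup.
#' @param modelPpd pixels per degree assumed by the model.
#' @return resized RGB array (identity when the factor is 1).
#' @export
rescaleForDva <- function(img, datasetPpd, modelPpd = 30) {
  if (datasetPpd <= 0 || modelPpd <= 0) stop("pixels-per-degree must be positive")
  img <- asRGBImage(img)
  f <- modelPpd / datasetPpd
  if (f == 1) return(img)
  nr <- round(dim(img)[1] * f); nc <- round(dim(img)[2] * f)
  out <- array(0, dim = c(nr, nc, 3L))
  for (ch in 1:3) out[, , ch] <- pmin(pmax(resizeMap(img[, , ch], nr, nc), 0), 1)
  out
}
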