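#' Multi-scale feature pyramid
#'
#' An ordered stack of 2-D activation maps for one feature channel, with
#' successive levels downsampled by a fixed factor (half-octave steps,
#' \eqn{\sqrt{2}}, by default). Level 1 is the full-resolution map.
#'
#' @slot levels list of numeric matrices, finest first.
#' @slot channel label of the feature housed (e.g. `"J"`, `"RG"`).
#' @slot scaleFactor linear downsampling factor between adjacent levels.
#' @export
setClass("FeaturePyramid",
  representation(levels = "list", channel = "character", scaleFactor = "numeric"),
  validity = function(object) {
    if (length(object@levels) < 1L) return("pyramid needs at least one level")
    if (!all(vapply(object@levels, is.matrix, logical(1))))
      return("all levels must be matrices")
    for (k in seq_along(object@levels)) {
      if (!all(is.finite(object@levels[[k]])))
        return(sprintf("non-finite values at level %d", k))
    }
    if (length(object@levels) > 1L) {
      d1 <- dim(object@levels[[1L]])
      for (k in seq_along(object@levels)[-1L]) {
        expect <- round(d1 / object@scaleFactor^(k - 1L))
        if (any(abs(dim(object@levels[[k]]) - expect) > 1))
          return(sprintf("level %d dimensions deviate from geometric scaling", k))
      }
    }
    TRUE
  }
)

#' Saliency map
#'
#' The model's final output: a non-negative 2-D map at input-image
#' resolution, together with the model variant that produced it.
#'
#' @slot values numeric matrix of non-negative saliency values.
#' @slot variant integer model variant (1 = all channels, 2 = spatial-pooling
#'   texture channel only).
#' @export
setClass("SaliencyMap",
  representation(values = "matrix", variant = "integer"),
  validity = function(object) {
    if (!all(is.finite(object@values))) return("non-finite saliency values")
    if (min(object@values) < 0) return("saliency values must be non-negative")
    if (!object@variant %in% c(1L, 2L)) return("variant must be 1 or 2")
    TRUE
  }
)

#' Eye-fixation set
#'
#' Discrete fixation points for one image, possibly from several observers.
#' Coordinates are 0-based pixels: `x` is the column, `y` the row.
#'
#' @slot points data.frame with columns `x`, `y`, `observer`.
#' @slot width,height image dimensions in pixels.
#' @export
setClass("FixationSet",
  representation(points = "data.frame", width = "integer", height = "integer"),
  validity = function(object) {
    p <- object@points
    if (!all(c("x", "y", "observer") %in% names(p)))
      return("points needs columns x, y, observer")
    if (nrow(p) > 0) {
      if (any(p$x < 0 | p$x > object@width - 1L | p$y < 0 | p$y > object@height - 1L))
        return("fixations out of image bounds")
    }
    TRUE
  }
)

#' @describeIn FeaturePyramid-class number of pyramid levels.
#' @param x a `FeaturePyramid`.
#' @export
setMethod("length", "FeaturePyramid", function(x) length(x@levels))

#' Access one level of a pyramid
#' @param pyr a `FeaturePyramid`.
#' @param k level index (1 = finest).
#' @return numeric matrix.
#' @export
pyramidLevel <- function(pyr, k) pyr@levels[[k]]

#' Extract the saliency values
#' @param x a `SaliencyMap`.
#' @return numeric matrix.
#' @export
salValues <- function(x) x@values

#' Fixation points as a data frame
#' @param x a `FixationSet`.
#' @return data.frame with 0-based `x`, `y` and `observer`.
#' @export
fixPoints <- function(x) x@points

#' Number of fixations
#' @param x a `FixationSet`.
#' @export
setMethod("length", "FixationSet", function(x) nrow(x@points))

setMethod("show", "FeaturePyramid", function(object) {
  d1 <- dim(object@levels[[1]])
  dn <- dim(object@levels[[length(object@levels)]])
  cat(sprintf("FeaturePyramid '%s': %d levels, %dx%d .. %dx%d (factor %.3f)\n",
              object@channel, length(object@levels), d1[1], d1[2],
              dn[1], dn[2], object@scaleFactor))
})

setMethod("show", "SaliencyMap", function(object) {
  cat(sprintf("SaliencyMap (model %d): %dx%d, max %.4g\n",
              object@variant, nrow(object@values), ncol(object@values),
              max(object@values)))
})

setMethod("show", "FixationSet", function(object) {
  cat(sprintf("FixationSet: %d fixations, %d observer(s), image %dx%d (WxH)\n",
              nrow(object@points), length(unique(object@points$observer)),
              object@width, object@height))
})

#' Construct a FixationSet
#'
#' @param x,y 0-based pixel coordinates (x = column, y = row). Fractional
#'   coordinates are rounded to the nearest pixel; out-of-bounds points are
#'   dropped with a message.
#' @param width,height image dimensions.
#' @param observer observer labels (recycled).
#' @return a `FixationSet`.
#' @export
fixationSet <- function(x, y, width, height, observer = 1L) {
  stopifnot(length(x) == length(y))
  x <- round(x); y <- round(y)
  observer <- rep_len(observer, length(x))
  keep <- x >= 0 & x <= width - 1 & y >= 0 & y <= height - 1
  if (any(!keep)) message(sum(!keep), " out-of-bounds fixation(s) dropped")
  methods::new("FixationSet",
    points = data.frame(x = x[keep], y = y[keep], observer = observer[keep]),
    width = as.integer(width), height = as.integer(height))
}

#' Read fixations from CSV
#'
#' Expects columns `image,observer,x,y` with 0-based pixel coordinates.
#'
#' @param path CSV path.
#' @param width,height image dimensions used for bounds checking.
#' @param image optional image id to filter on.
#' @return a `FixationSet`.
#' @export
readFixationCSV <- function(path, width, height, image = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image", "observer", "x", "y")
  if (!all(need %in% names(d))) stop("fixation CSV needs columns image,observer,x,y")
  if (!is.null(image)) d <- d[d$image == image, , drop = FALSE]
  fixationSet(d$x, d$y, width, height, observer = d$observer)
}

#' Write fixations to CSV
#'
#' @param fix a `FixationSet`.
#' @param path output path.
#' @param image image id written in the `image` column.
#' @export
writeFixationCSV <- function(fix, path, image = "img") {
  p <- fixPoints(fix)
  utils::write.csv(
    data.frame(image = image, observer = p$observer, x = p$x, y = p$y),
    path, row.names = FALSE)
  invisible(path)
}
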