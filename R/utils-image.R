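# Orientation set used throughout: 0, 45, 90, 135 degrees (radians).
THETAS <- c(0, pi / 4, pi / 2, 3 * pi / 4)
THETA_NAMES <- c("0", "45", "90", "135")

#' Reflect-pad a matrix
#'
#' Pads a matrix by mirroring rows and columns about the edges (the first and
#' last row/column are not duplicated). Padding cannot exceed `dim - 1`; larger
#' requests are clipped.
#'
#' @param m numeric matrix.
#' @param py,px padding in rows and columns.
#' @return padded matrix.
#' @keywords internal
padReflect <- function(m, py, px = py) {
  nr <- nrow(m); nc <- ncol(m)
  py <- min(py, nr - 1L); px <- min(px, nc - 1L)
  ri <- c(rev(seq_len(py) + 1L), seq_len(nr), nr - seq_len(py))
  ci <- c(rev(seq_len(px) + 1L), seq_len(nc), nc - seq_len(px))
  m[ri, ci, drop = FALSE]
}

rot180 <- function(k) k[rev(seq_len(nrow(k))), rev(seq_len(ncol(k))), drop = FALSE]

#' 2-D convolution with reflected borders
#'
#' Convolves `m` with an odd-sized kernel, treating pixels beyond the border
#' as mirror reflections of the interior. Output has the size of `m`.
#'
#' @param m numeric matrix.
#' @param k odd-dimension kernel matrix.
#' @return filtered matrix.
#' @keywords internal
convolveReflect <- function(m, k) {
  ry <- (nrow(k) - 1L) %/% 2L
  rx <- (ncol(k) - 1L) %/% 2L
  p <- padReflect(m, ry, rx)
  f <- EBImage::filter2(p, k, boundary = 0)
  py <- min(ry, nrow(m) - 1L); px <- min(rx, ncol(m) - 1L)
  f[py + seq_len(nrow(m)), px + seq_len(ncol(m)), drop = FALSE]
}

# Cross-correlation ("gather") convention: out(p) = sum_off w(off) m(p + off),
# with w indexed so that w[center + off] holds the weight of offset `off`.
xcorrReflect <- function(m, w) convolveReflect(m, rot180(w))

#' Resize a 2-D map
#'
#' Bilinear resize that preserves constants. When shrinking and
#' `smooth = TRUE`, the map is first low-pass filtered with a Gaussian whose
#' width matches the downsampling factor
#' (\eqn{\sigma = 0.5\sqrt{f^2 - 1}}), the standard anti-aliasing
#' pre-filter for pyramid construction; plain bilinear sampling would alias
#' thin structure at non-integer factors.
#'
#' @param m numeric matrix.
#' @param nr,nc target numbers of rows and columns.
#' @param smooth apply the anti-aliasing pre-filter when shrinking.
#' @return resized matrix.
#' @export
resizeMap <- function(m, nr, nc, smooth = TRUE) {
  nr <- as.integer(round(nr)); nc <- as.integer(round(nc))
  stopifnot(nr >= 1L, nc >= 1L)
  if (nr == nrow(m) && nc == ncol(m)) return(m)
  f <- max(nrow(m) / nr, ncol(m) / nc)
  if (smooth && f > 1) {
    sigma <- 0.5 * sqrt(f^2 - 1)
    if (sigma > 0.1) m <- gaussianBlurMap(m, sigma)
  }
  out <- EBImage::resize(m, w = nr, h = nc, filter = "bilinear", antialias = FALSE)
  matrix(as.numeric(out), nr, nc)
}

#' Gaussian-blur a map
#'
#' Isotropic Gaussian blur with the kernel truncated at four standard
#' deviations and reflecting borders. `sigma = 0` returns the input.
#'
#' @param m numeric matrix.
#' @param sigma standard deviation in pixels.
#' @return blurred matrix.
#' @export
gaussianBlurMap <- function(m, sigma) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(m)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  k <- outer(g, g)
  convolveReflect(m, k)
}

# Mean of local maxima other than the global max. Local maxima are positive
# pixels equal to the max over a (2r+1)^2 neighbourhood; a connected plateau
# counts as a single maximum (bilinear upsampling creates flat-topped peaks).
meanOtherLocalMaxima <- function(m, r = 3L) {
  if (max(m) <= 0) return(0)
  d <- EBImage::dilate(m, matrix(1, 2L * r + 1L, 2L * r + 1L))
  mask <- m >= d - 1e-12 & m > 0
  lab <- EBImage::bwlabel(mask)
  if (max(lab) <= 1L) return(0)
  vals <- as.numeric(tapply(m[mask], as.vector(lab)[mask], max))
  # drop a single instance of the global maximum
  vals <- vals[-which.max(vals)]
  mean(vals)
}

# Can a reflect-padded convolution with kernel k be applied to m?
# (padding is capped at dim-1, so the padded image must still fit the kernel)
fitsKernel <- function(m, k) {
  all(dim(m) + 2L * (dim(m) - 1L) >= dim(k)) || all(dim(m) >= dim(k))
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

halfRectify <- function(m) {
  m[m < 0] <- 0
  m
}

assertFiniteMap <- function(m, what = "map") {
  if (!all(is.finite(m))) stop(sprintf("non-finite values in %s", what))
  invisible(m)
}
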