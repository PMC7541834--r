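circularFootprint <- function(diameter) {
  r <- (diameter - 1L) %/% 2L
  dy <- matrix(rep(-r:r, times = diameter), diameter, diameter)
  dx <- matrix(rep(-r:r, each = diameter), diameter, diameter)
  matrix(as.numeric(sqrt(dy^2 + dx^2) <= diameter / 2), diameter, diameter)
}

#' Circular max-pooling
#'
#' Grayscale dilation with a circular footprint (pixel offsets whose
#' Euclidean distance from the centre is at most `diameter/2`), stride 1,
#' reflecting borders. This is the complex-cell MAX operator of the texture
#' channels: the 15-px default matches a complex-cell receptive field about
#' the size of the 13-px simple-cell (Gabor) support.
#'
#' @param m numeric matrix, at least `diameter` on each side.
#' @param diameter odd footprint diameter in pixels.
#' @return matrix of the same size.
#' @export
circularMaxPool <- function(m, diameter = 15L) {
  stopifnot(diameter %% 2L == 1L)
  if (min(dim(m)) < diameter) {
    warning(sprintf("map %dx%d smaller than pooling footprint; skipped",
                    nrow(m), ncol(m)))
    return(NULL)
  }
  r <- (diameter - 1L) %/% 2L
  p <- padReflect(m, r, r)
  d <- EBImage::dilate(p, circularFootprint(diameter))
  d[r + seq_len(nrow(m)), r + seq_len(ncol(m)), drop = FALSE]
}

#' Shrink texture maps to the second-order scale
#'
#' Second-order texture mechanisms operate roughly eight times coarser than
#' first-order features, so pooled texture maps are resized by `factor`
#' (default 1/7.5). After this shrink the 15-px pooling footprint spans
#' about 2 px, which lets the grouping stage's center-surround cells (up to
#' five octaves) cover coarse second-order structure.
#'
#' @param m numeric matrix (or NULL, passed through).
#' @param factor linear resize factor in (0, 1).
#' @return resized matrix, or NULL if the result would be under 4 px.
#' @export
downscaleTextureMap <- function(m, factor = 1 / 7.5) {
  stopifnot(factor > 0, factor < 1)
  if (is.null(m)) return(NULL)
  nr <- round(nrow(m) * factor); nc <- round(ncol(m) * factor)
  if (min(nr, nc) < 4L) {
    warning("texture map under 4 px after downscale; skipped")
    return(NULL)
  }
  resizeMap(m, nr, nc)
}

poolAndShrink <- function(m, cfg) {
  if (is.null(m)) return(NULL)
  p <- circularMaxPool(m, cfg$texture$diameter)
  downscaleTextureMap(p, cfg$texture$resize_factor)
}

#' Spatial-pooling texture channel (J1)
#'
#' \eqn{J_{1,\theta,C}^k = MAX[F^{opp\,k}_{\theta,C}]}: circular max-pooling
#' of each opponency map, then the 1/7.5 shrink. The pooling fills in the
#' interior of a region of coherent orientation, turning line elements into
#' a surface signal a figure-ground stage can group.
#'
#' @param opp orientation-keyed list of per-level opponency maps
#'   (one source channel), as returned by [orientationOpponency()].
#' @param cfg a [protoConfig()] list.
#' @return same structure: per orientation, per level, pooled + shrunk maps.
#' @export
spatialPoolingChannel <- function(opp, cfg = protoConfig()) {
  lapply(opp, function(lv) lapply(lv, poolAndShrink, cfg = cfg))
}

#' Cross-scale texture channel (J2)
#'
#' Emphasises locations where similar elements repeat across scales:
#' the pixel-wise product of an opponency map with the same-orientation map
#' two levels (one octave) coarser, resized onto the finer map's grid, then
#' max-pooled and shrunk. Levels 1-4 pair with level k+2; levels 5-7 pair
#' with level k-4.
#'
#' @inheritParams spatialPoolingChannel
#' @return per orientation, per level, pooled + shrunk product maps.
#' @export
crossScaleChannel <- function(opp, cfg = protoConfig()) {
  n <- length(opp[[1]])
  if (n < 7L) stop("cross-scale channel requires a 7-level pyramid")
  lapply(opp, function(lv) {
    lapply(seq_len(n), function(k) {
      kp <- if (k <= 4L) k + 2L else k - 4L
      a <- lv[[k]]; b <- lv[[kp]]
      if (is.null(a) || is.null(b)) return(NULL)
      prod <- a * resizeMap(b, nrow(a), ncol(a))
      poolAndShrink(prod, cfg)
    })
  })
}

#' Cross-orientation texture channel (J3)
#'
#' Products of opponency maps at non-orthogonal orientation pairs
#' \eqn{(\theta, \phi)} with \eqn{\theta \in \{0, \pi/2\}} and
#' \eqn{\phi \in \{\pi/4, 3\pi/4\}} at the same level, max-pooled and
#' shrunk. Responds where two distinct orientations coexist, a signature of
#' complex texture processed in area V2.
#'
#' @inheritParams spatialPoolingChannel
#' @return list keyed `"0x45"`, `"0x135"`, `"90x45"`, `"90x135"`, each a
#'   per-level list of pooled + shrunk maps.
#' @export
crossOrientationChannel <- function(opp, cfg = protoConfig()) {
  pairs <- list(c("0", "45"), c("0", "135"), c("90", "45"), c("90", "135"))
  names(pairs) <- vapply(pairs, paste, "", collapse = "x")
  n <- length(opp[[1]])
  lapply(pairs, function(pr) {
    lapply(seq_len(n), function(k) {
      a <- opp[[pr[1]]][[k]]; b <- opp[[pr[2]]][[k]]
      if (is.null(a) || is.null(b)) return(NULL)
      poolAndShrink(a * b, cfg)
    })
  })
}

#' All texture channels for one source channel
#'
#' @param opp opponency maps for one source channel.
#' @param cfg a [protoConfig()] list; `cfg$texture$channels` selects the
#'   subset of `J1`, `J2`, `J3` computed.
#' @return named list with elements among `J1`, `J2`, `J3`.
#' @export
textureChannelSet <- function(opp, cfg = protoConfig()) {
  want <- cfg$texture$channels
  out <- list()
  if ("J1" %in% want) out$J1 <- spatialPoolingChannel(opp, cfg)
  if ("J2" %in% want) out$J2 <- crossScaleChannel(opp, cfg)
  if ("J3" %in% want) out$J3 <- crossOrientationChannel(opp, cfg)
  out
}
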