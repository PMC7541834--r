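asLevelList <- function(x) {
  if (methods::is(x, "FeaturePyramid")) x@levels else x
}

#' Oriented edge responses
#'
#' Odd-symmetric Gabor filtering of every pyramid level at the four
#' orientations; the response magnitude marks boundaries (luminance or
#' texture discontinuities) regardless of contrast polarity. `theta` labels
#' the direction of modulation, so the `"0"` detector responds to vertical
#' boundaries.
#'
#' @param pyr a [FeaturePyramid-class] or plain list of matrices (NULL
#'   entries are skipped).
#' @param cfg a [protoConfig()] list.
#' @param bank optional precomputed odd-Gabor bank.
#' @return list over orientations of per-level edge-magnitude maps.
#' @export
edgeResponses <- function(pyr, cfg = protoConfig(), bank = NULL) {
  levels <- asLevelList(pyr)
  if (is.null(bank)) bank <- gaborBank(cfg, "odd")
  ext <- nrow(bank[[1]])
  lapply(bank, function(k) {
    lapply(levels, function(m) {
      if (is.null(m) || min(dim(m)) < ext) return(NULL)
      abs(convolveReflect(m, k))
    })
  })
}

#' Center-surround decomposition
#'
#' Difference-of-Gaussians style ON/OFF maps computed across pyramid levels:
#' for level k the surround is the mean of the coarser levels within
#' `spanOctaves` octaves (half-octave steps), resized back onto level k's
#' grid. `ON = max(center - surround, 0)`, `OFF = max(surround - center, 0)`,
#' so `ON - OFF` equals the unrectified difference. The coarsest level has no
#' surround and yields zero maps.
#'
#' @param pyr a [FeaturePyramid-class] or list of matrices.
#' @param spanOctaves surround reach in octaves (3 for low-level channels,
#'   5 for texture channels, clipped to the available depth).
#' @param warn warn when the requested span is clipped.
#' @return list with per-level `on` and `off` map lists.
#' @export
centerSurround <- function(pyr, spanOctaves = 3L, warn = FALSE) {
  levels <- asLevelList(pyr)
  n <- length(levels)
  reach <- 2L * spanOctaves
  if (warn && reach > n - 1L)
    warning("center-surround span exceeds pyramid depth; clipped")
  on <- off <- vector("list", n)
  for (k in seq_len(n)) {
    m <- levels[[k]]
    if (is.null(m)) next
    sidx <- seq(k + 1L, min(n, k + reach))
    sidx <- sidx[sidx > k & sidx <= n]
    sidx <- Filter(function(j) !is.null(levels[[j]]), sidx)
    if (length(sidx) == 0L) {
      on[[k]] <- off[[k]] <- matrix(0, nrow(m), ncol(m))
      next
    }
    surround <- Reduce(`+`, lapply(sidx, function(j)
      resizeMap(levels[[j]], nrow(m), ncol(m)))) / length(sidx)
    d <- m - surround
    on[[k]] <- halfRectify(d)
    off[[k]] <- halfRectify(-d)
  }
  list(on = on, off = off)
}

# Annular von Mises kernel in gather convention: mass on rings at the given
# radii, angularly concentrated around direction mu (atan2(dy, dx), y down).
# Normalised to unit sum.
vonMisesRing <- function(radii, kappa, mu) {
  rmax <- max(radii)
  ext <- as.integer(2L * ceiling(2 * rmax) + 1L)
  r0 <- (ext - 1L) %/% 2L
  dy <- matrix(rep(-r0:r0, times = ext), ext, ext)
  dx <- matrix(rep(-r0:r0, each = ext), ext, ext)
  rr <- sqrt(dy^2 + dx^2)
  phi <- atan2(dy, dx)
  w <- matrix(0, ext, ext)
  for (R in radii) {
    ring <- exp(-(rr - R)^2 / (2 * (R / 3)^2))
    w <- w + ring * exp(kappa * cos(phi - mu))
  }
  w / sum(w)
}

# One kernel per side direction (theta and theta + pi for each orientation).
groupingKernels <- function(cfg) {
  g <- cfg$grouping
  angles <- c(THETAS, THETAS + pi)
  names(angles) <- c(THETA_NAMES, paste0(THETA_NAMES, "pi"))
  lapply(angles, function(mu) vonMisesRing(g$annulus_radii, g$vonmises_kappa, mu))
}

sideAngleNames <- function() {
  # for orientation theta, the two candidate figure sides lie along theta
  # (the modulation direction) and theta + pi
  list("0" = c("0", "0pi"), "45" = c("45", "45pi"),
       "90" = c("90", "90pi"), "135" = c("135", "135pi"))
}

#' Border-ownership assignment
#'
#' Splits each oriented edge response into two ownership-side responses.
#' The combined ON + OFF center-surround activity is integrated over an
#' annular half-field on each side of the edge (von Mises weighted), and the
#' side with more figure-like activity wins a subtractive competition:
#' \eqn{BO_{side} = E \cdot \lfloor 1 + w (A_{side} - A_{other}) \rfloor}.
#'
#' @param edges oriented edge maps from [edgeResponses()].
#' @param cs center-surround pair from [centerSurround()].
#' @param cfg a [protoConfig()] list.
#' @param kernels optional precomputed [groupingKernels()].
#' @return list over orientations; each a list with `side1`/`side2` per-level
#'   map lists (side1 lies along theta, side2 along theta + pi).
#' @export
borderOwnership <- function(edges, cs, cfg = protoConfig(), kernels = NULL) {
  if (is.null(kernels)) kernels <- groupingKernels(cfg)
  w <- cfg$grouping$bo_weight
  minsz <- cfg$grouping$min_map_size
  n <- length(cs$on)
  sides <- sideAngleNames()
  # side-field activity per level per direction, computed once
  S <- lapply(seq_len(n), function(k) {
    if (is.null(cs$on[[k]])) return(NULL)
    s <- cs$on[[k]] + cs$off[[k]]
    if (max(s) > 0) s / max(s) else s
  })
  A <- lapply(names(kernels), function(ang) {
    lapply(seq_len(n), function(k) {
      if (is.null(S[[k]]) || min(dim(S[[k]])) < minsz ||
          !fitsKernel(S[[k]], kernels[[ang]])) return(NULL)
      xcorrReflect(S[[k]], kernels[[ang]])
    })
  })
  names(A) <- names(kernels)
  lapply(stats::setNames(names(edges), names(edges)), function(th) {
    s12 <- sides[[th]]
    side1 <- side2 <- vector("list", n)
    for (k in seq_len(n)) {
      e <- edges[[th]][[k]]
      if (is.null(e) || is.null(A[[s12[1]]][[k]])) next
      a1 <- A[[s12[1]]][[k]]; a2 <- A[[s12[2]]][[k]]
      # purely subtractive competition: edges flanked by symmetric surround
      # activity cast no ownership vote at all
      side1[[k]] <- e * halfRectify(w * (a1 - a2))
      side2[[k]] <- e * halfRectify(w * (a2 - a1))
    }
    list(side1 = side1, side2 = side2)
  })
}

#' Grouping-cell activity
#'
#' Grouping cells integrate ownership-weighted edge activity along annuli:
#' a cell at the centre of a proto-object collects border-ownership votes
#' whose preferred side points back at it, across all orientations and both
#' sides. Output peaks at proto-object centres.
#'
#' @param bo border-ownership maps from [borderOwnership()].
#' @param cfg a [protoConfig()] list.
#' @param kernels optional precomputed [groupingKernels()].
#' @return per-level list of grouping maps (NULL at skipped levels).
#' @export
groupingActivity <- function(bo, cfg = protoConfig(), kernels = NULL) {
  if (is.null(kernels)) kernels <- groupingKernels(cfg)
  sides <- sideAngleNames()
  # vote kernel gathers from the direction opposite the ownership side
  flip <- c("0" = "0pi", "45" = "45pi", "90" = "90pi", "135" = "135pi",
            "0pi" = "0", "45pi" = "45", "90pi" = "90", "135pi" = "135")
  n <- max(vapply(bo, function(b) length(b$side1), integer(1)))
  out <- vector("list", n)
  for (k in seq_len(n)) {
    acc <- NULL
    for (th in names(bo)) {
      s12 <- sides[[th]]
      for (i in 1:2) {
        m <- bo[[th]][[c("side1", "side2")[i]]][[k]]
        if (is.null(m)) next
        v <- xcorrReflect(m, kernels[[flip[[s12[i]]]]])
        acc <- if (is.null(acc)) v else acc + v
      }
    }
    out[[k]] <- acc
  }
  out
}

#' Full grouping chain for one feature pyramid
#'
#' Edge detection, center-surround decomposition, border ownership and
#' grouping integration, applied level-wise to one feature channel.
#'
#' @param pyr a [FeaturePyramid-class] or list of matrices.
#' @param cfg a [protoConfig()] list.
#' @param spanOctaves center-surround span for this channel.
#' @param oddBank,kernels optional precomputed odd-Gabor bank and grouping
#'   kernels.
#' @return per-level list of grouping maps.
#' @export
groupPyramid <- function(pyr, cfg = protoConfig(),
                         spanOctaves = cfg$grouping$cs_span_lowlevel,
                         oddBank = NULL, kernels = NULL) {
  edges <- edgeResponses(pyr, cfg, bank = oddBank)
  cs <- centerSurround(pyr, spanOctaves)
  bo <- borderOwnership(edges, cs, cfg, kernels = kernels)
  groupingActivity(bo, cfg, kernels = kernels)
}
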