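#' Peak-promoting map normalization
#'
#' Rescales a map to \[0, 1\] and multiplies it by
#' \eqn{(M - \bar m)^2}, where \eqn{M} is the global maximum (1 after
#' rescaling) and \eqn{\bar m} the mean of the other local maxima. Maps with
#' one strong peak keep their weight; maps with many competing peaks are
#' suppressed. All-zero maps are returned unchanged.
#'
#' @param m numeric non-negative matrix.
#' @param maximaRadius neighbourhood radius used to detect local maxima.
#' @return weighted matrix.
#' @export
normalizeMap <- function(m, maximaRadius = 3L) {
  if (is.null(m) || max(m) <= 0) return(m)
  v <- m / max(m)
  w <- (1 - meanOtherLocalMaxima(v, maximaRadius))^2
  # sparsity factor: broad structureless hills are not proto-objects and
  # should not outvote maps with compact peaks
  w <- w * (1 - mean(v))^4
  v * w
}

flattenMaps <- function(x) {
  # collect all matrices from arbitrarily nested lists
  if (is.matrix(x)) return(list(x))
  if (is.null(x)) return(list())
  unlist(lapply(x, flattenMaps), recursive = FALSE)
}

# a "feature" is one grouping pyramid: a list whose non-NULL elements are
# matrices (per-level grouping maps); collect all features in a class
collectFeatures <- function(x) {
  if (is.matrix(x)) return(list(list(x)))
  if (is.null(x)) return(list())
  isPyramid <- all(vapply(x, function(e) is.null(e) || is.matrix(e), logical(1)))
  if (isPyramid) return(list(x))
  unlist(lapply(x, collectFeatures), recursive = FALSE)
}

#' Combine grouping maps into a saliency map
#'
#' Within each channel class every grouping map is normalized
#' ([normalizeMap()]), upsampled to the output grid and summed; the class
#' conspicuity maps are normalized again and averaged (equal weights by
#' default). The result is rescaled to a \[0, 1\] maximum.
#'
#' @param groupingMaps named list of channel classes; each element holds
#'   grouping maps (matrices, possibly nested in lists with NULLs).
#' @param variant model variant id (1 or 2), stored in the result.
#' @param dims output `c(rows, cols)`.
#' @param cfg a [protoConfig()] list (class weights).
#' @return a [SaliencyMap-class].
#' @export
combineChannels <- function(groupingMaps, variant, dims, cfg = protoConfig()) {
  if (length(groupingMaps) == 0L) stop("empty channel roster")
  classMaps <- lapply(groupingMaps, function(cls) {
    feats <- collectFeatures(cls)
    acc <- matrix(0, dims[1], dims[2])
    for (ft in feats) {
      # across-scale combination: levels of one feature are summed on a
      # common grid without uniqueness weighting, so structure that repeats
      # across scales reinforces while single-level flukes are diluted
      facc <- matrix(0, dims[1], dims[2])
      nlev <- 0L
      for (m in ft) {
        if (is.null(m) || max(m) <= 0) next
        facc <- facc + resizeMap(m / max(m), dims[1], dims[2])
        nlev <- nlev + 1L
      }
      if (nlev == 0L) next
      # uniqueness weighting across features: maps with one dominant
      # proto-object keep their weight, cluttered maps are suppressed
      nf <- normalizeMap(facc)
      if (max(nf) > 0) acc <- acc + nf
    }
    acc
  })
  wts <- cfg$combine$class_weights
  if (is.null(wts)) wts <- rep(1, length(classMaps))
  wts <- rep_len(wts, length(classMaps)) / sum(rep_len(wts, length(classMaps)))
  out <- matrix(0, dims[1], dims[2])
  for (i in seq_along(classMaps)) {
    nm <- normalizeMap(classMaps[[i]])
    out <- out + wts[i] * nm
  }
  out <- halfRectify(out)
  if (max(out) > 0) out <- out / max(out)
  methods::new("SaliencyMap", values = out, variant = as.integer(variant))
}

#' Compute a proto-object saliency map
#'
#' Runs the full pipeline: intensity/color decomposition, half-octave
#' pyramids, even-Gabor filtering with orthogonal-orientation opponency,
#' texture channels, border-ownership grouping per channel, and conspicuity
#' combination. Model variant 1 uses the low-level classes (intensity,
#' color, orientation) plus the three texture classes; variant 2 uses only
#' the spatial-pooling texture channel. The forward pass is deterministic.
#'
#' @param img RGB array in \[0, 1\] (`rows x cols x 3`) or a grayscale
#'   matrix.
#' @param variant 1 or 2 (default 2, the stronger variant).
#' @param cfg a [protoConfig()] list.
#' @return a [SaliencyMap-class] at input resolution.
#' @examples
#' stim <- textureFigureStimulus(canvas = 128L, figure = c(16, 16, 64, 64))
#' sal <- computeSaliency(stim$image, variant = 2, cfg = protoConfig(nLevels = 4L))
#' @export
computeSaliency <- function(img, variant = 2L, cfg = protoConfig()) {
  img <- asRGBImage(img)
  variant <- as.integer(variant)
  stopifnot(variant %in% c(1L, 2L))
  dims <- dim(img)[1:2]
  n <- cfg$nLevels

  J <- intensityChannel(img)
  colorMaps <- colorOpponencyChannels(img, cfg$color_threshold)
  sources <- list(J = J, RG = colorMaps$RG, GR = colorMaps$GR,
                  BY = colorMaps$BY, YB = colorMaps$YB)
  sources <- sources[intersect(c("J", cfg$texture$sources),
                               names(sources))]

  evenBank <- gaborBank(cfg, "even")
  oddBank <- gaborBank(cfg, "odd")
  kernels <- groupingKernels(cfg)

  pyramids <- list()
  opp <- list()
  for (nm in names(sources)) {
    if (max(sources[[nm]]) <= 0 && nm != "J") next  # all-zero source
    pyramids[[nm]] <- buildPyramid(sources[[nm]], n, channel = nm,
                                   scaleFactor = cfg$scaleFactor)
    resp <- gaborResponses(pyramids[[nm]], cfg, bank = evenBank)
    opp[[nm]] <- orientationOpponency(resp)
  }

  wantTex <- if (variant == 2L) "J1" else cfg$texture$channels
  texCfg <- cfg
  texCfg$texture$channels <- wantTex
  texture <- lapply(opp, textureChannelSet, cfg = texCfg)

  groupTex <- function(chan) {
    # chan: per-source list of per-orientation per-level maps
    lapply(texture, function(src) {
      if (is.null(src[[chan]])) return(NULL)
      lapply(src[[chan]], function(levelList)
        groupPyramid(levelList, cfg, spanOctaves = cfg$grouping$cs_span_texture,
                     oddBank = oddBank, kernels = kernels))
    })
  }

  classes <- list()
  if (variant == 1L) {
    classes$intensity <- groupPyramid(pyramids$J, cfg,
                                      spanOctaves = cfg$grouping$cs_span_lowlevel,
                                      oddBank = oddBank, kernels = kernels)
    colorGroups <- lapply(intersect(c("RG", "GR", "BY", "YB"), names(pyramids)),
                          function(nm) groupPyramid(pyramids[[nm]], cfg,
                            spanOctaves = cfg$grouping$cs_span_lowlevel,
                            oddBank = oddBank, kernels = kernels))
    if (length(colorGroups)) classes$color <- colorGroups
    classes$orientation <- lapply(opp$J, function(levelList)
      groupPyramid(levelList, cfg, spanOctaves = cfg$grouping$cs_span_lowlevel,
                   oddBank = oddBank, kernels = kernels))
    for (chan in wantTex) classes[[chan]] <- groupTex(chan)
  } else {
    classes$J1 <- groupTex("J1")
  }

  combineChannels(classes, variant, dims, cfg)
}

#' Write a saliency map to disk
#'
#' Writes `PREFIX.png` (min-max normalized 16-bit grayscale, for
#' visualization) and `PREFIX.csv` (raw values, row-major, comma-separated —
#' what the metrics consume).
#'
#' @param sal a [SaliencyMap-class].
#' @param prefix output path prefix.
#' @return the two paths, invisibly.
#' @export
writeSaliency <- function(sal, prefix) {
  v <- salValues(sal)
  rng <- range(v)
  vn <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
  png <- paste0(prefix, ".png")
  csv <- paste0(prefix, ".csv")
  EBImage::writeImage(t(vn), png, bits.per.sample = 16L)
  utils::write.table(v, csv, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(c(png = png, csv = csv))
}

#' Read a saliency map written by [writeSaliency()]
#'
#' @param csv path to the raw CSV matrix.
#' @param variant variant id to record.
#' @return a [SaliencyMap-class].
#' @export
readSaliencyCSV <- function(csv, variant = 2L) {
  v <- as.matrix(utils::read.table(csv, sep = ","))
  dimnames(v) <- NULL
  methods::new("SaliencyMap", values = v, variant = as.integer(variant))
}
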