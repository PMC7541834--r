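# splat anti-aliased line segments onto a canvas (bilinear point splatting);
# wrap = TRUE draws on a torus so ink density stays uniform at the borders
drawSegment <- function(canvas, cy, cx, theta, len, width = 1, step = 0.25,
                        wrap = FALSE) {
  dirY <- sin(theta); dirX <- cos(theta)
  # perpendicular offsets realise stroke width
  nY <- -dirX; nX <- dirY
  ts <- seq(-len / 2, len / 2, by = step)
  ws <- seq(-(width - 1) / 2, (width - 1) / 2, length.out = max(1, ceiling(width / step)))
  H <- nrow(canvas); W <- ncol(canvas)
  for (wo in ws) {
    py <- cy + ts * dirY + wo * nY
    px <- cx + ts * dirX + wo * nX
    y0 <- floor(py); x0 <- floor(px)
    fy <- py - y0; fx <- px - x0
    amp <- step / length(ws)
    for (d in 1:4) {
      yy <- y0 + (d > 2); xx <- x0 + (d %% 2 == 0)
      wgt <- (if (d > 2) fy else 1 - fy) * (if (d %% 2 == 0) fx else 1 - fx)
      if (wrap) {
        yy <- ((yy - 1) %% H) + 1
        xx <- ((xx - 1) %% W) + 1
        ok <- rep_len(TRUE, length(yy))
      } else {
        ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
      }
      if (any(ok)) {
        idx <- cbind(yy[ok], xx[ok])
        canvas[idx] <- canvas[idx] + amp * wgt[ok]
      }
    }
  }
  canvas
}

grayToRGB <- function(m) array(rep(m, 3L), dim = c(dim(m), 3L))

#' Texture-defined figure stimulus
#'
#' A canvas tiled with short oriented line segments on a jittered grid:
#' background segments at `thetaBg`, segments whose grid cell centre falls
#' inside the figure rectangle at `thetaFg`. Line density is identical
#' inside and outside, so the figure is invisible to mean luminance and only
#' defined by orientation — the second-order figure-ground stimulus.
#'
#' @param canvas canvas size in pixels (scalar or `c(rows, cols)`).
#' @param figure figure rectangle `c(row0, col0, height, width)`, 1-based;
#'   default: a square in the lower-left quadrant.
#' @param thetaFg,thetaBg segment orientations (radians) inside/outside the
#'   figure.
#' @param lineLength,lineWidth,spacing segment geometry in pixels.
#' @param jitter maximal uniform grid jitter in pixels.
#' @param contrast peak segment luminance in (0, 1\].
#' @param seed RNG seed (jitter only); the generator is deterministic given
#'   the seed.
#' @return list with `image` (RGB array), `mask` (logical matrix, TRUE
#'   inside the figure) and `segments` (placement log: centre, orientation,
#'   in-figure flag).
#' @export
textureFigureStimulus <- function(canvas = 512L, figure = NULL,
                                  thetaFg = pi / 4, thetaBg = 3 * pi / 4,
                                  lineLength = 9, lineWidth = 1, spacing = 12,
                                  jitter = 2, contrast = 1, seed = 1L) {
  if (spacing < lineWidth) stop("segment spacing smaller than line width")
  dims <- if (length(canvas) == 1L) c(canvas, canvas) else canvas[1:2]
  H <- as.integer(dims[1]); W <- as.integer(dims[2])
  if (is.null(figure)) {
    side <- floor(min(H, W) * 0.375)
    figure <- c(H - floor(H * 0.125) - side, floor(W * 0.125) + 1L, side, side)
  }
  # tile the canvas exactly (toroidal grid): uniform segment density,
  # so mean luminance carries no information about the figure
  ncy <- max(2L, round(H / spacing)); ncx <- max(2L, round(W / spacing))
  cys <- (seq_len(ncy) - 0.5) * H / ncy
  cxs <- (seq_len(ncx) - 0.5) * W / ncx
  # snap the figure to cell boundaries and classify cells by their
  # unjittered centres, so segment ink stays on its own side of the border
  snap <- function(v, n, len) round(v * n / len) * len / n
  r0 <- snap(figure[1] - 1, ncy, H); r1 <- snap(figure[1] - 1 + figure[3], ncy, H)
  q0 <- snap(figure[2] - 1, ncx, W); q1 <- snap(figure[2] - 1 + figure[4], ncx, W)
  mask <- matrix(FALSE, H, W)
  mask[(floor(r0) + 1L):ceiling(r1), (floor(q0) + 1L):ceiling(q1)] <- TRUE
  img <- matrix(0, H, W)
  segs <- withSeed(seed, {
    log <- vector("list", length(cys) * length(cxs))
    i <- 0L
    for (cy in cys) for (cx in cxs) {
      i <- i + 1L
      inside <- cy > r0 && cy < r1 && cx > q0 && cx < q1
      jy <- cy + stats::runif(1, -jitter, jitter)
      jx <- cx + stats::runif(1, -jitter, jitter)
      th <- if (inside) thetaFg else thetaBg
      img <- drawSegment(img, jy, jx, th, lineLength, lineWidth, wrap = TRUE)
      log[[i]] <- data.frame(cy = jy, cx = jx, theta = th, inFigure = inside)
    }
    do.call(rbind, log)
  })
  img <- pmin(img, 1) * contrast
  list(image = grayToRGB(img), mask = mask, segments = segs)
}

# render one glyph ("L" or "+") of given arm length into a canvas
drawGlyph <- function(canvas, cy, cx, kind, size, strokeWidth = 1) {
  half <- size / 2
  if (kind == "+") {
    canvas <- drawSegment(canvas, cy, cx, 0, size, strokeWidth)
    canvas <- drawSegment(canvas, cy, cx, pi / 2, size, strokeWidth)
  } else { # "L": corner at lower-left of the glyph box
    canvas <- drawSegment(canvas, cy + half, cx, 0, size, strokeWidth)      # bottom bar
    canvas <- drawSegment(canvas, cy, cx - half, pi / 2, size, strokeWidth) # left bar
  }
  canvas
}

#' Pop-out array stimulus
#'
#' A jittered regular grid of "L" glyphs with exactly one "+" glyph.
#' Both glyphs are two equal strokes, so their ink is matched; the "+" pops
#' out through its element configuration, not through luminance.
#'
#' @param canvas canvas size (scalar or `c(rows, cols)`).
#' @param pitch grid pitch in pixels.
#' @param glyphSize stroke length of each glyph in pixels.
#' @param strokeWidth stroke width in pixels.
#' @param jitter maximal uniform position jitter in pixels.
#' @param seed RNG seed (target cell and jitter).
#' @return list with `image` (RGB array), `target` (0-based `c(x, y)` of the
#'   "+" centre), `glyphSize` and `glyphs` (placement log: kind and centre of
#'   every glyph).
#' @export
popoutArrayStimulus <- function(canvas = 224L, pitch = 28L, glyphSize = 11,
                                strokeWidth = 1, jitter = 3, seed = 1L) {
  dims <- if (length(canvas) == 1L) c(canvas, canvas) else canvas[1:2]
  H <- as.integer(dims[1]); W <- as.integer(dims[2])
  margin <- pitch / 2 + glyphSize / 2 + jitter
  if (H - 2 * margin < pitch || W - 2 * margin < pitch)
    stop("grid too dense for canvas")
  cys <- seq(margin, H - margin, by = pitch)
  cxs <- seq(margin, W - margin, by = pitch)
  if (length(cys) < 2L || length(cxs) < 2L) stop("grid too dense for canvas")
  img <- matrix(0, H, W)
  res <- withSeed(seed, {
    tgt <- c(sample(seq_along(cys), 1L), sample(seq_along(cxs), 1L))
    target <- NULL
    glyphs <- vector("list", length(cys) * length(cxs))
    n <- 0L
    for (i in seq_along(cys)) for (j in seq_along(cxs)) {
      jy <- cys[i] + stats::runif(1, -jitter, jitter)
      jx <- cxs[j] + stats::runif(1, -jitter, jitter)
      kind <- if (i == tgt[1] && j == tgt[2]) "+" else "L"
      img <- drawGlyph(img, jy, jx, kind, glyphSize, strokeWidth)
      if (kind == "+") target <- c(jx, jy)
      n <- n + 1L
      glyphs[[n]] <- data.frame(kind = kind, cy = jy, cx = jx)
    }
    list(target = target, glyphs = do.call(rbind, glyphs))
  })
  list(image = grayToRGB(pmin(img, 1)), target = res$target - 1,
       glyphSize = glyphSize, glyphs = res$glyphs)
}

#' Blob stimulus
#'
#' A luminance or color disc on a uniform background, with an optional
#' soft (Gaussian) edge.
#'
#' @param canvas canvas size (scalar or `c(rows, cols)`).
#' @param center disc centre `c(row, col)`, 1-based; default: canvas centre.
#' @param radius disc radius in pixels.
#' @param color RGB triplet of the disc.
#' @param background RGB triplet (or scalar gray) of the background.
#' @param edgeSigma Gaussian softening of the disc boundary (0 = hard edge).
#' @return list with `image` (RGB array) and `mask` (logical disc mask).
#' @export
blobStimulus <- function(canvas = 128L, center = NULL, radius = 24,
                         color = c(1, 1, 1), background = 0, edgeSigma = 1) {
  dims <- if (length(canvas) == 1L) c(canvas, canvas) else canvas[1:2]
  H <- dims[1]; W <- dims[2]
  if (is.null(center)) center <- c((H + 1) / 2, (W + 1) / 2)
  color <- rep_len(color, 3L)
  bg <- rep_len(background, 3L)
  yy <- matrix(rep(seq_len(H), times = W), H, W)
  xx <- matrix(rep(seq_len(W), each = H), H, W)
  d <- sqrt((yy - center[1])^2 + (xx - center[2])^2)
  a <- if (edgeSigma > 0) 1 / (1 + exp((d - radius) / edgeSigma)) else as.numeric(d <= radius)
  img <- array(0, dim = c(H, W, 3L))
  for (ch in 1:3) img[, , ch] <- bg[ch] + (color[ch] - bg[ch]) * a
  list(image = pmin(pmax(img, 0), 1), mask = d <= radius)
}

#' Sinusoidal grating
#'
#' @param canvas canvas size (scalar or `c(rows, cols)`).
#' @param wavelength grating period in pixels.
#' @param theta modulation direction in radians (0 = modulating along
#'   columns, i.e. vertical stripes).
#' @param phase phase offset in radians.
#' @param contrast Michelson contrast in \[0, 1\].
#' @return grayscale matrix in \[0, 1\].
#' @export
gratingStimulus <- function(canvas = 64L, wavelength = 4, theta = 0,
                            phase = 0, contrast = 1) {
  dims <- if (length(canvas) == 1L) c(canvas, canvas) else canvas[1:2]
  H <- dims[1]; W <- dims[2]
  yy <- matrix(rep(seq_len(H) - 1, times = W), H, W)
  xx <- matrix(rep(seq_len(W) - 1, each = H), H, W)
  xp <- xx * cos(theta) + yy * sin(theta)
  0.5 + 0.5 * contrast * cos(2 * pi * xp / wavelength + phase)
}

#' Plaid (superimposed gratings)
#'
#' @inheritParams gratingStimulus
#' @param theta1,theta2 the two component orientations.
#' @return grayscale matrix in \[0, 1\] (mean of the two gratings).
#' @export
plaidStimulus <- function(canvas = 64L, wavelength = 4, theta1 = 0,
                          theta2 = pi / 4, contrast = 1) {
  (gratingStimulus(canvas, wavelength, theta1, contrast = contrast) +
     gratingStimulus(canvas, wavelength, theta2, contrast = contrast)) / 2
}

#' Sample synthetic fixations from a ground-truth density
#'
#' Draws `n` i.i.d. fixation points from a probability map by inverse-CDF
#' sampling on the flattened density; fully deterministic given the seed.
#'
#' @param density non-negative matrix with positive sum (normalized
#'   internally).
#' @param n number of fixations.
#' @param seed RNG seed.
#' @param observer observer label(s) for the sampled points.
#' @return a [FixationSet-class].
#' @export
syntheticFixations <- function(density, n, seed = 1L, observer = 1L) {
  if (min(density) < 0 || sum(density) <= 0 || !all(is.finite(density)))
    stop("degenerate density")
  p <- as.vector(density) / sum(density)
  cdf <- cumsum(p)
  idx <- withSeed(seed, findInterval(stats::runif(n), cdf) + 1L)
  idx <- pmin(idx, length(p))
  H <- nrow(density)
  row <- ((idx - 1L) %% H) + 1L
  col <- ((idx - 1L) %/% H) + 1L
  fixationSet(x = col - 1L, y = row - 1L, width = ncol(density),
              height = H, observer = observer)
}
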