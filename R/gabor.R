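#' Gabor kernel
#'
#' Samples a Gabor filter
#' \deqn{g_\theta(x,y) = \exp\!\left(-\frac{x'^2 + \gamma^2 y'^2}{2\sigma^2}\right)
#'       \cos(\omega x')}
#' with \eqn{x' = x\cos\theta + y\sin\theta}, \eqn{y' = -x\sin\theta + y\cos\theta}
#' on an `extent x extent` grid centred at the origin
#' (\eqn{\omega = 2\pi/\lambda}). The even (cosine) kernel is made zero-mean by
#' subtracting its mean so that constant inputs produce no response; the odd
#' (sine) kernel is zero-mean by antisymmetry.
#'
#' Matrix rows index y (down), columns x (right), so `theta = 0` responds to
#' structure modulating along image columns, i.e. vertical lines.
#'
#' @param theta orientation in radians.
#' @param wavelength carrier wavelength \eqn{\lambda} in pixels.
#' @param sigma Gaussian envelope standard deviation in pixels.
#' @param gamma spatial aspect ratio of the envelope.
#' @param extent odd kernel size in pixels.
#' @param phase `"even"` (cosine) or `"odd"` (sine).
#' @return `extent x extent` numeric kernel.
#' @export
gaborKernel <- function(theta, wavelength = 4, sigma = 13 / 6, gamma = 1,
                        extent = 13L, phase = c("even", "odd")) {
  phase <- match.arg(phase)
  stopifnot(wavelength > 0, extent %% 2L == 1L)
  r <- (extent - 1L) %/% 2L
  omega <- 2 * pi / wavelength
  x <- matrix(rep(-r:r, each = extent), extent, extent)  # columns: x
  y <- matrix(rep(-r:r, times = extent), extent, extent) # rows: y
  xp <- x * cos(theta) + y * sin(theta)
  yp <- -x * sin(theta) + y * cos(theta)
  env <- exp(-(xp^2 + gamma^2 * yp^2) / (2 * sigma^2))
  k <- if (phase == "even") env * cos(omega * xp) else env * sin(omega * xp)
  k - mean(k)
}

gaborBank <- function(cfg, phase = "even") {
  g <- cfg$gabor
  lapply(stats::setNames(THETAS, THETA_NAMES), function(th)
    gaborKernel(th, g$wavelength, g$sigma, g$gamma, g$extent, phase))
}

#' Oriented Gabor responses of a pyramid
#'
#' Convolves every pyramid level with the even-symmetric Gabor bank at the
#' four orientations \eqn{\{0, \pi/4, \pi/2, 3\pi/4\}} and takes the
#' magnitude. Filter sizes are fixed across levels; scale selectivity comes
#' from the pyramid. Levels smaller than the kernel are skipped (`NULL` with
#' a warning).
#'
#' @param pyr a [FeaturePyramid-class].
#' @param cfg a [protoConfig()] list (uses `cfg$gabor`).
#' @param bank optional precomputed kernel list (from repeated calls).
#' @return list over orientations (`"0"`, `"45"`, `"90"`, `"135"`), each a
#'   list over levels of non-negative matrices.
#' @export
gaborResponses <- function(pyr, cfg = protoConfig(), bank = NULL) {
  if (is.null(bank)) bank <- gaborBank(cfg, "even")
  ext <- nrow(bank[[1]])
  lapply(bank, function(k) {
    lapply(pyr@levels, function(m) {
      if (min(dim(m)) < ext) {
        warning(sprintf("level %dx%d smaller than %d-px Gabor kernel; skipped",
                        nrow(m), ncol(m), ext))
        return(NULL)
      }
      abs(convolveReflect(m, k))
    })
  })
}

#' Orthogonal-orientation opponency
#'
#' For each orientation \eqn{\theta}, the half-wave-rectified difference with
#' its orthogonal partner,
#' \eqn{F^{opp}_\theta = \lfloor F_\theta - F_{\theta+\pi/2} \rfloor},
#' modelling inhibition between simple cells of antagonistic orientation
#' preference. Even Gabors are \eqn{\pi}-periodic, so the pairs are
#' (0, 90) and (45, 135) degrees, each taken in both directions.
#'
#' @param resp orientation-keyed response list from [gaborResponses()].
#' @return list with the same structure, half-wave rectified.
#' @export
orientationOpponency <- function(resp) {
  partner <- c("0" = "90", "90" = "0", "45" = "135", "135" = "45")
  out <- lapply(stats::setNames(names(resp), names(resp)), function(th) {
    a <- resp[[th]]; b <- resp[[partner[[th]]]]
    lapply(seq_along(a), function(k) {
      if (is.null(a[[k]]) || is.null(b[[k]])) return(NULL)
      halfRectify(a[[k]] - b[[k]])
    })
  })
  out
}
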