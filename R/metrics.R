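fixIndex <- function(fix) {
  p <- fixPoints(fix)
  cbind(p$y + 1L, p$x + 1L)  # 0-based (x, y) -> 1-based (row, col)
}

#' Fixation density map
#'
#' Blurs the binary fixation-location map with an isotropic Gaussian
#' (truncated at 4 standard deviations, reflecting borders). The blur sigma
#' is conventionally one degree of visual angle in pixels.
#'
#' @param fix a [FixationSet-class] with at least one point.
#' @param sigmaPx Gaussian standard deviation in pixels.
#' @return numeric matrix `height x width` with non-negative values.
#' @export
fixationMap <- function(fix, sigmaPx) {
  if (length(fix) == 0L) stop("empty fixation set")
  m <- matrix(0, fix@height, fix@width)
  ij <- fixIndex(fix)
  for (i in seq_len(nrow(ij))) m[ij[i, 1], ij[i, 2]] <- m[ij[i, 1], ij[i, 2]] + 1
  if (sigmaPx > 0) m <- halfRectify(gaussianBlurMap(m, sigmaPx))
  m
}

#' Pearson correlation between two maps
#'
#' \eqn{CC = \sigma(X, Y) / (\sigma(X)\,\sigma(Y))} over pixels.
#' Returns `NA` with a warning for constant maps.
#'
#' @param X,Y equally-sized numeric matrices.
#' @return correlation in \[-1, 1\], or `NA`.
#' @export
metricCC <- function(X, Y) {
  stopifnot(all(dim(X) == dim(Y)))
  if (stats::sd(X) == 0 || stats::sd(Y) == 0) {
    warning("CC undefined for a constant map")
    return(NA_real_)
  }
  stats::cor(as.vector(X), as.vector(Y))
}

#' Similarity metric between two maps
#'
#' Both maps are normalized to unit sum; the score is the summed pixel-wise
#' minimum, \eqn{\sum_i \min(X_i, Y_i) \in [0, 1]}. Identical maps score 1;
#' maps with disjoint support score 0.
#'
#' @param X,Y non-negative matrices with positive sums.
#' @return similarity in \[0, 1\].
#' @export
metricSIM <- function(X, Y) {
  stopifnot(all(dim(X) == dim(Y)))
  if (min(X) < -1e-9 || min(Y) < -1e-9) stop("SIM requires non-negative maps")
  X <- halfRectify(X); Y <- halfRectify(Y)  # absorb FFT round-off
  sx <- sum(X); sy <- sum(Y)
  if (sx <= 0 || sy <= 0) stop("SIM requires maps with positive sum")
  sum(pmin(X / sx, Y / sy))
}

#' Normalized scan-path saliency
#'
#' The saliency map is z-scored (zero mean, unit standard deviation) and
#' averaged at the fixated pixels. Chance level is 0.
#'
#' @param sal numeric saliency matrix.
#' @param fix a [FixationSet-class].
#' @return mean z-scored saliency at fixations, `NA` for a constant map.
#' @export
metricNSS <- function(sal, fix) {
  if (length(fix) == 0L) stop("empty fixation set")
  s <- stats::sd(sal)
  if (s == 0) {
    warning("NSS undefined for a constant map")
    return(NA_real_)
  }
  z <- (sal - mean(sal)) / s
  mean(z[fixIndex(fix)])
}

#' Kullback-Leibler divergence between fixation and saliency maps
#'
#' Both maps are normalized to unit sum and compared as
#' \eqn{\sum_i Y_i \log\{(\epsilon + Y_i) / (\epsilon + X_i)\}}, with the
#' fixation map `Y` as reference. Small values are better; identical maps
#' give 0.
#'
#' @param sal saliency map `X` (non-negative, positive sum).
#' @param fixmap fixation density map `Y` (non-negative, positive sum).
#' @param epsilon regularization constant (> 0).
#' @return divergence (>= 0 up to epsilon effects).
#' @export
metricKLD <- function(sal, fixmap, epsilon = 1e-12) {
  if (epsilon <= 0) stop("epsilon must be positive")
  stopifnot(all(dim(sal) == dim(fixmap)))
  sal <- halfRectify(sal); fixmap <- halfRectify(fixmap)  # FFT round-off
  X <- sal / sum(sal)
  Y <- fixmap / sum(fixmap)
  sum(Y * log((epsilon + Y) / (epsilon + X)))
}

# trapezoidal AUC from saliency values at positive/negative pixels;
# thresholds at unique values, ties included at once
rocAUC <- function(pos, neg) {
  th <- sort(unique(c(pos, neg)), decreasing = TRUE)
  tpr <- c(0, vapply(th, function(t) mean(pos >= t), numeric(1)), 1)
  fpr <- c(0, vapply(th, function(t) mean(neg >= t), numeric(1)), 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Shuffled AUC
#'
#' ROC area with positives taken at this image's fixation pixels and
#' negatives sampled from fixation locations of *other* images, which
#' cancels center bias (chance level 0.5). As many negatives as positives
#' are drawn per repetition; the score is averaged over `nSplits` seeded
#' repetitions.
#'
#' @param sal saliency matrix.
#' @param fix positive fixations ([FixationSet-class]).
#' @param otherFix list of [FixationSet-class] from other images (the
#'   negative pool), or a single `FixationSet`.
#' @param nSplits number of negative-sampling repetitions.
#' @param seed RNG seed for the negative sampling.
#' @return mean AUC in \[0, 1\].
#' @export
metricSAUC <- function(sal, fix, otherFix, nSplits = 100L, seed = 1L) {
  if (length(fix) == 0L) stop("no positive fixations")
  if (methods::is(otherFix, "FixationSet")) otherFix <- list(otherFix)
  pool <- do.call(rbind, lapply(otherFix, function(f) {
    p <- fixPoints(f)
    cbind(pmin(pmax(p$y + 1L, 1L), nrow(sal)), pmin(pmax(p$x + 1L, 1L), ncol(sal)))
  }))
  if (is.null(pool) || nrow(pool) == 0L) stop("empty negative fixation pool")
  pos <- sal[fixIndex(fix)]
  withSeed(seed, {
    mean(vapply(seq_len(nSplits), function(s) {
      idx <- sample.int(nrow(pool), length(pos), replace = nrow(pool) < length(pos))
      rocAUC(pos, sal[pool[idx, , drop = FALSE]])
    }, numeric(1)))
  })
}

#' Distance-to-center weight map
#'
#' \deqn{DTC(i,j) = 1 - \sqrt{(i - H/2)^2 + (j - W/2)^2} \big/
#'       \sqrt{(H/2)^2 + (W/2)^2}}
#' with 0-based row/column indices and real-valued halves: 1 at the image
#' centre, 0 at the corners, radially decreasing. Multiplying a saliency map
#' by this weight compensates model comparisons for the human center bias.
#'
#' @param H,W image height and width (>= 2).
#' @return `H x W` matrix of weights in \[0, 1\].
#' @export
dtcMap <- function(H, W) {
  stopifnot(H >= 2, W >= 2)
  i <- matrix(rep(0:(H - 1), times = W), H, W)
  j <- matrix(rep(0:(W - 1), each = H), H, W)
  1 - sqrt((i - H / 2)^2 + (j - W / 2)^2) / sqrt((H / 2)^2 + (W / 2)^2)
}

metricAtSigma <- function(metric, sal, fix, fixmap, sigmaPx, dtc, epsilon,
                          otherFix = NULL, nSplits = 100L, seed = 1L) {
  s <- if (sigmaPx > 0) gaussianBlurMap(sal, sigmaPx) else sal
  if (dtc && metric != "sauc") s <- s * dtcMap(nrow(s), ncol(s))
  switch(metric,
    cc = metricCC(s, fixmap),
    sim = metricSIM(s, fixmap),
    nss = metricNSS(s, fix),
    kld = metricKLD(s, fixmap, epsilon),
    sauc = metricSAUC(s, fix, otherFix, nSplits, seed),
    stop("unknown metric: ", metric))
}

#' Blur-sigma sweep
#'
#' Evaluates one metric over a sweep of Gaussian blur widths applied to the
#' saliency map: sigma from 0.01 to 0.20 of the image width in steps of 0.01
#' (20 points) for CC/SIM/NSS/KLD, and up to 0.08 (8 points) for sAUC.
#' Optional distance-to-center re-weighting is applied to every metric
#' except sAUC, which compensates center bias by construction. The best
#' sigma maximizes the score (minimizes it for KLD).
#'
#' @param sal saliency matrix.
#' @param fix ground-truth fixations ([FixationSet-class]).
#' @param metric one of `"cc"`, `"sim"`, `"nss"`, `"kld"`, `"sauc"`.
#' @param fixmapSigmaPx blur sigma for the ground-truth fixation map.
#' @param dtc apply distance-to-center re-weighting.
#' @param otherFix negative pool for sAUC.
#' @param epsilon KLD regularizer.
#' @param nSplits,seed sAUC negative-sampling controls.
#' @return list with `curve` (data.frame `sigma_frac`, `score`),
#'   `best_sigma_frac` and `best_score`.
#' @export
blurSweep <- function(sal, fix, metric = c("cc", "sim", "nss", "kld", "sauc"),
                      fixmapSigmaPx = 0.035 * ncol(sal), dtc = FALSE,
                      otherFix = NULL, epsilon = 1e-12,
                      nSplits = 100L, seed = 1L) {
  metric <- match.arg(metric)
  fracs <- if (metric == "sauc") seq(0.01, 0.08, by = 0.01) else seq(0.01, 0.20, by = 0.01)
  fixmap <- if (metric %in% c("cc", "sim", "kld")) fixationMap(fix, fixmapSigmaPx) else NULL
  scores <- vapply(fracs, function(f)
    metricAtSigma(metric, sal, fix, fixmap, f * ncol(sal), dtc, epsilon,
                  otherFix, nSplits, seed), numeric(1))
  best <- if (metric == "kld") which.min(scores) else which.max(scores)
  list(curve = data.frame(sigma_frac = fracs, score = scores),
       best_sigma_frac = fracs[best], best_score = scores[best])
}

#' Inter-observer three-fold baseline
#'
#' Observers are split into three groups; each group in turn serves as
#' ground truth while the pooled fixations of the other two act as the
#' predicting "model". Scores are averaged over the three rotations. No
#' distance-to-center re-weighting is applied — human data already carry the
#' center bias.
#'
#' @param fix a [FixationSet-class] holding at least 3 observers.
#' @param metric one of `"cc"`, `"sim"`, `"nss"`, `"kld"`, `"sauc"`.
#' @param sigmaPx blur sigma (pixels) for both predictor and truth maps.
#' @param otherFix negative pool for sAUC.
#' @param epsilon KLD regularizer.
#' @param seed controls the observer split and sAUC sampling.
#' @param nSplits sAUC repetitions.
#' @return mean score over the three rotations.
#' @export
interObserverThreefold <- function(fix, metric = c("cc", "sim", "nss", "kld", "sauc"),
                                   sigmaPx = 0.035 * fix@width, otherFix = NULL,
                                   epsilon = 1e-12, seed = 1L, nSplits = 100L) {
  metric <- match.arg(metric)
  p <- fixPoints(fix)
  obs <- unique(p$observer)
  if (length(obs) < 3L) stop("inter-observer baseline needs at least 3 observers")
  groups <- withSeed(seed, split(sample(obs), rep_len(1:3, length(obs))))
  subsetFix <- function(keep) {
    q <- p[p$observer %in% keep, , drop = FALSE]
    methods::new("FixationSet", points = q, width = fix@width, height = fix@height)
  }
  scores <- vapply(1:3, function(g) {
    truth <- subsetFix(groups[[g]])
    pred <- subsetFix(unlist(groups[-g]))
    predMap <- fixationMap(pred, sigmaPx)
    truthMap <- if (metric %in% c("cc", "sim", "kld")) fixationMap(truth, sigmaPx) else NULL
    metricAtSigma(metric, predMap, truth, truthMap, 0, dtc = FALSE, epsilon,
                  otherFix, nSplits, seed)
  }, numeric(1))
  mean(scores)
}

#' Evaluate saliency maps against fixations
#'
#' Per-image metric report: for each requested metric, either a fixed-blur
#' score or a full blur sweep with the best score retained.
#'
#' @param sal saliency matrix.
#' @param fix ground truth ([FixationSet-class]).
#' @param metrics character vector among `cc`, `sim`, `nss`, `kld`, `sauc`.
#' @param dtc apply distance-to-center re-weighting (not for sAUC).
#' @param blurSweep run the blur sweep (otherwise sigma 0).
#' @param otherFix negative pool for sAUC.
#' @param epsilon KLD regularizer.
#' @param nSplits,seed sAUC controls.
#' @return data.frame `metric, sigma_frac, dtc, score`.
#' @export
metricReport <- function(sal, fix, metrics = c("cc", "sim", "nss", "kld", "sauc"),
                         dtc = FALSE, blurSweep = TRUE, otherFix = NULL,
                         epsilon = 1e-12, nSplits = 100L, seed = 1L) {
  rows <- lapply(metrics, function(met) {
    if (met == "sauc" && is.null(otherFix))
      return(NULL)
    if (blurSweep) {
      sw <- protosal::blurSweep(sal, fix, met, dtc = dtc, otherFix = otherFix,
                                epsilon = epsilon, nSplits = nSplits, seed = seed)
      data.frame(metric = met, sigma_frac = sw$best_sigma_frac,
                 dtc = dtc && met != "sauc", score = sw$best_score)
    } else {
      fm <- if (met %in% c("cc", "sim", "kld"))
        fixationMap(fix, 0.035 * ncol(sal)) else NULL
      data.frame(metric = met, sigma_frac = 0,
                 dtc = dtc && met != "sauc",
                 score = metricAtSigma(met, sal, fix, fm, 0, dtc, epsilon,
                                       otherFix, nSplits, seed))
    }
  })
  do.call(rbind, rows)
}
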