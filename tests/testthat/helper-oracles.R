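# Independent brute-force oracles used to pin down the vectorised /
# library-backed implementations. Deliberately naive: explicit loops,
# no shared code with the package internals.

# reflect-padded circular max pool, exhaustive double loop
bfCircularMaxPool <- function(m, diameter = 15L) {
  r <- (diameter - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  reflect <- function(i, n) {
    # mirror about the edges without repeating the border pixel
    while (i < 1L || i > n) {
      if (i < 1L) i <- 2L - i
      if (i > n) i <- 2L * n - i
    }
    i
  }
  out <- matrix(0, H, W)
  offs <- which(outer((-r:r)^2, (-r:r)^2, `+`) <= (diameter / 2)^2, arr.ind = TRUE)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    best <- -Inf
    for (o in seq_len(nrow(offs))) {
      yy <- reflect(i + offs[o, 1] - r - 1L, H)
      xx <- reflect(j + offs[o, 2] - r - 1L, W)
      if (m[yy, xx] > best) best <- m[yy, xx]
    }
    out[i, j] <- best
  }
  out
}

# elementwise half-wave rectified difference
bfOpponency <- function(a, b) {
  out <- matrix(0, nrow(a), ncol(a))
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    d <- a[i, j] - b[i, j]
    out[i, j] <- if (d > 0) d else 0
  }
  out
}

bfSIM <- function(X, Y) {
  X <- X / sum(X); Y <- Y / sum(Y)
  s <- 0
  for (i in seq_along(X)) s <- s + min(X[i], Y[i])
  s
}

bfKLD <- function(X, Y, eps) {
  X <- X / sum(X); Y <- Y / sum(Y)
  s <- 0
  for (i in seq_along(X)) s <- s + Y[i] * log((eps + Y[i]) / (eps + X[i]))
  s
}

bfDTC <- function(H, W) {
  out <- matrix(0, H, W)
  for (i in 0:(H - 1)) for (j in 0:(W - 1)) {
    out[i + 1, j + 1] <- 1 - sqrt((i - H / 2)^2 + (j - W / 2)^2) /
      sqrt((H / 2)^2 + (W / 2)^2)
  }
  out
}

# AUC by exhaustive pair counting (ties count half) — equivalent to the
# trapezoid over unique thresholds
bfAUC <- function(pos, neg) {
  s <- 0
  for (p in pos) for (n in neg) {
    if (p > n) s <- s + 1 else if (p == n) s <- s + 0.5
  }
  s / (length(pos) * length(neg))
}

# deterministic test fixtures
seededMatrix <- function(nr, nc, seed = 1) {
  set.seed(seed)
  matrix(runif(nr * nc), nr, nc)
}

# synthetic opponency stacks (4 orientations x n levels of random maps)
makeFakeOpp <- function(n = 7, dims = rep(40, n), seed = 31) {
  set.seed(seed)
  thetas <- c("0", "45", "90", "135")
  lapply(stats::setNames(thetas, thetas), function(th)
    lapply(seq_len(n), function(k) matrix(runif(dims[k]^2), dims[k], dims[k])))
}

# across-scale sum of grouping maps, as used by the conspicuity combination
groupSumAcc <- function(map, cfg = protoConfig(), n = 5L) {
  g <- groupPyramid(buildPyramid(map, n), cfg)
  acc <- matrix(0, nrow(map), ncol(map))
  for (m in g) {
    if (is.null(m) || max(m) <= 0) next
    acc <- acc + resizeMap(m / max(m), nrow(map), ncol(map))
  }
  acc
}
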