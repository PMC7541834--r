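test_that("fixation maps are Gaussian, linear and centred on the points", {
  fix <- fixationSet(x = 32, y = 32, width = 65, height = 65)
  fm <- fixationMap(fix, sigmaPx = 5)
  expect_equal(which(fm == max(fm), arr.ind = TRUE)[1, ],
               c(row = 33, col = 33))
  ray <- fm[33, 33:53]  # within the truncated kernel support
  expect_true(all(diff(ray) < 1e-12))
  tiny <- fixationMap(fix, sigmaPx = 1e-4)
  expect_gt(tiny[33, 33] / sum(tiny), 0.999)
  fix2 <- fixationSet(x = c(10, 50), y = c(10, 50), width = 65, height = 65)
  fa <- fixationMap(fixationSet(10, 10, 65, 65), 5)
  fb <- fixationMap(fixationSet(50, 50, 65, 65), 5)
  expect_equal(fixationMap(fix2, 5), fa + fb, tolerance = 1e-12)
  expect_error(fixationMap(fixationSet(numeric(0), numeric(0), 65, 65), 5),
               "empty")
})

test_that("CC behaves as a Pearson correlation over pixels", {
  X <- seededMatrix(32, 32, 51)
  expect_equal(metricCC(X, X), 1)
  expect_equal(metricCC(X, -X + 2), -1)
  Y <- seededMatrix(256, 256, 52); Z <- seededMatrix(256, 256, 53)
  expect_lt(abs(metricCC(Y, Z)), 0.05)
  expect_warning(v <- metricCC(matrix(1, 4, 4), X[1:4, 1:4]), "constant")
  expect_true(is.na(v))
})

test_that("SIM matches its definition and the brute-force oracle", {
  X <- seededMatrix(64, 64, 54)
  expect_equal(metricSIM(X, X), 1, tolerance = 1e-12)
  A <- matrix(0, 8, 8); A[, 1:4] <- 1
  B <- matrix(0, 8, 8); B[, 5:8] <- 1
  expect_equal(metricSIM(A, B), 0)
  Y <- seededMatrix(64, 64, 55)
  expect_equal(metricSIM(X, Y), bfSIM(X, Y), tolerance = 1e-12)
  expect_equal(metricSIM(X, Y), metricSIM(Y, X), tolerance = 1e-12)
  expect_error(metricSIM(X * 0, Y), "positive sum")
})

test_that("NSS is a z-scored mean with affine invariance", {
  sal <- seededMatrix(64, 64, 56)
  all <- expand.grid(x = 0:63, y = 0:63)
  fixAll <- fixationSet(all$x, all$y, 64, 64)
  expect_equal(metricNSS(sal, fixAll), 0, tolerance = 1e-12)
  onehot <- matrix(0, 64, 64); onehot[20, 30] <- 1
  onehot <- onehot + seededMatrix(64, 64, 57) * 1e-3
  peak <- fixationSet(29, 19, 64, 64)
  expect_gt(metricNSS(onehot, peak), 10)
  fix <- fixationSet(c(5, 40), c(7, 33), 64, 64)
  expect_equal(metricNSS(sal, fix), metricNSS(3.7 * sal + 0.4, fix),
               tolerance = 1e-9)
})

test_that("KLD follows Eq-style regularised divergence", {
  X <- seededMatrix(48, 48, 58)
  expect_equal(metricKLD(X, X), 0, tolerance = 1e-12)
  Y <- seededMatrix(48, 48, 59)
  expect_equal(metricKLD(X, Y, 1e-12), bfKLD(X, Y, 1e-12), tolerance = 1e-12)
  expect_gt(abs(metricKLD(X, Y) - metricKLD(Y, X)), 1e-6)  # asymmetric
  conc <- matrix(1e-9, 32, 32); conc[5, 5] <- 1
  sal <- matrix(1, 32, 32); sal[5, 5] <- 1e-9
  k1 <- metricKLD(sal, conc, 1e-6)
  k2 <- metricKLD(sal, conc, 1e-12)
  expect_gt(k2, k1)   # divergence grows as epsilon shrinks
  expect_gt(k2, 5)
  expect_error(metricKLD(X, Y, 0), "positive")
})

test_that("sAUC matches pair counting and is rank invariant", {
  sal <- seededMatrix(32, 32, 60)
  pos <- fixationSet(c(3, 10, 20, 25, 30, 4, 17, 9, 22, 12),
                     c(5, 12, 25, 3, 18, 28, 7, 15, 21, 9), 32, 32)
  neg <- fixationSet(c(1, 6, 13, 19, 27, 31, 2, 8, 24, 16),
                     c(2, 30, 11, 26, 4, 14, 20, 23, 6, 29), 32, 32)
  got <- metricSAUC(sal, pos, list(neg), nSplits = 1L, seed = 1L)
  pv <- sal[cbind(fixPoints(pos)$y + 1, fixPoints(pos)$x + 1)]
  nv <- sal[cbind(fixPoints(neg)$y + 1, fixPoints(neg)$x + 1)]
  expect_equal(got, bfAUC(pv, nv), tolerance = 1e-12)
  mono <- metricSAUC(log1p(sal * 9), pos, list(neg), nSplits = 1L, seed = 1L)
  expect_equal(got, mono, tolerance = 1e-12)
  sep <- fixationMap(pos, 2)
  expect_gt(metricSAUC(sep, pos, list(neg), nSplits = 20L, seed = 2L), 0.9)
  expect_error(metricSAUC(sal, pos, list(), 1L, 1L), "empty")
})

test_that("the DTC map matches the closed form", {
  d <- dtcMap(64, 48)
  expect_equal(d[33, 25], 1)  # 0-based (32, 24) is exactly (H/2, W/2)
  expect_equal(d[1, 1], 0)
  expect_equal(d, bfDTC(64, 48), tolerance = 1e-12)
  expect_true(all(d >= 0 & d <= 1))
  # radially non-increasing from the centre along a row through it
  mid <- d[33, 25:48]
  expect_true(all(diff(mid) <= 1e-12))
})

test_that("blur sweep runs 20 points (8 for sAUC) and tracks the optimum", {
  set.seed(61)
  truthMap <- matrix(0, 64, 64); truthMap[30:34, 40:44] <- 1
  fix <- syntheticFixations(truthMap, 30, seed = 3)
  sal <- fixationMap(fix, 2)
  for (met in c("cc", "sim", "nss", "kld")) {
    sw <- blurSweep(sal, fix, met)
    expect_equal(nrow(sw$curve), 20L)
    expect_equal(sw$curve$sigma_frac, seq(0.01, 0.20, by = 0.01))
    idx <- if (met == "kld") which.min(sw$curve$score) else which.max(sw$curve$score)
    expect_equal(sw$best_sigma_frac, sw$curve$sigma_frac[idx])
  }
  other <- syntheticFixations(matrix(1, 64, 64), 200, seed = 4)
  swa <- blurSweep(sal, fix, "sauc", otherFix = list(other), nSplits = 5L)
  expect_equal(nrow(swa$curve), 8L)
  expect_equal(max(swa$curve$sigma_frac), 0.08)
})

test_that("DTC re-weighting applies to all metrics except sAUC", {
  set.seed(62)
  truthMap <- matrix(0, 64, 64); truthMap[10:18, 10:18] <- 1  # off centre
  fix <- syntheticFixations(truthMap, 40, seed = 5)
  sal <- fixationMap(fix, 2)
  other <- syntheticFixations(matrix(1, 64, 64), 300, seed = 6)
  ccPlain <- blurSweep(sal, fix, "cc", dtc = FALSE)$best_score
  ccDtc <- blurSweep(sal, fix, "cc", dtc = TRUE)$best_score
  expect_false(isTRUE(all.equal(ccPlain, ccDtc)))
  sPlain <- blurSweep(sal, fix, "sauc", dtc = FALSE, otherFix = list(other),
                      nSplits = 3L, seed = 7L)$curve$score
  sDtc <- blurSweep(sal, fix, "sauc", dtc = TRUE, otherFix = list(other),
                    nSplits = 3L, seed = 7L)$curve$score
  expect_equal(sPlain, sDtc, tolerance = 1e-12)
})

test_that("inter-observer three-fold rotates groups and averages", {
  # all observers fixate the same pixel: SIM = 1 in every rotation
  fix <- fixationSet(rep(32, 6), rep(32, 6), 64, 64, observer = 1:6)
  expect_equal(interObserverThreefold(fix, "sim", sigmaPx = 3), 1,
               tolerance = 1e-9)
  # six synthetic observers, oracle recomputes the rotation by hand
  truthMap <- matrix(0, 64, 64); truthMap[20:40, 20:40] <- 1
  pts <- lapply(1:6, function(o) {
    f <- syntheticFixations(truthMap, 15, seed = 100 + o, observer = o)
    fixPoints(f)
  })
  allp <- do.call(rbind, pts)
  fix6 <- fixationSet(allp$x, allp$y, 64, 64, observer = allp$observer)
  got <- interObserverThreefold(fix6, "sim", sigmaPx = 3, seed = 9L)
  groups <- protosal:::withSeed(9L, split(sample(1:6), rep_len(1:3, 6)))
  manual <- mean(sapply(1:3, function(g) {
    truth <- allp[allp$observer %in% groups[[g]], ]
    pred <- allp[!allp$observer %in% groups[[g]], ]
    tm <- fixationMap(fixationSet(truth$x, truth$y, 64, 64), 3)
    pm <- fixationMap(fixationSet(pred$x, pred$y, 64, 64), 3)
    metricSIM(pm, tm)
  }))
  expect_equal(got, manual, tolerance = 1e-12)
  fix2 <- fixationSet(c(1, 2), c(1, 2), 64, 64, observer = 1:2)
  expect_error(interObserverThreefold(fix2, "sim"), "3 observers")
})

test_that("fixation CSV round-trips with bounds checking", {
  d <- withr::local_tempdir()
  fix <- fixationSet(c(3, 10.4, 20), c(5, 7.6, 30), 32, 32, observer = c(1, 1, 2))
  p <- file.path(d, "fix.csv")
  writeFixationCSV(fix, p, image = "im1")
  back <- readFixationCSV(p, 32, 32, image = "im1")
  expect_equal(fixPoints(back), fixPoints(fix))
  expect_message(fixationSet(c(5, 40), c(5, 5), 32, 32), "dropped")
})
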