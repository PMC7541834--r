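discImage <- function(canvas = 96, center = NULL, radius = 16, neg = FALSE) {
  b <- blobStimulus(canvas, center = center, radius = radius, edgeSigma = 1)
  m <- intensityChannel(b$image)
  if (neg) m <- 1 - m
  list(map = m, mask = b$mask, center = if (is.null(center))
    c((canvas + 1) / 2, (canvas + 1) / 2) else center)
}

test_that("edge responses vanish on constants and ring object boundaries", {
  cfg <- protoConfig()
  e0 <- edgeResponses(list(matrix(0.4, 48, 48)), cfg)
  for (th in names(e0)) expect_lt(max(e0[[th]][[1]]), 1e-12)

  step <- cbind(matrix(0, 48, 24), matrix(1, 48, 24))
  es <- edgeResponses(list(step), cfg)
  # a vertical step modulates along x: the theta = 0 detector wins
  mid <- es[["0"]][[1]][24, ]
  expect_equal(which.max(mid), 24, tolerance = 1)
  expect_gt(max(es[["0"]][[1]][24, ]), 5 * max(es[["90"]][[1]][24, 15:34]))

  d <- discImage(96, radius = 20)
  etot <- Reduce(`+`, lapply(edgeResponses(list(d$map), cfg), `[[`, 1))
  # compare the radius of peak edge activity with a discrete gradient oracle
  gy <- d$map[3:96, ] - d$map[1:94, ]
  gx <- d$map[, 3:96] - d$map[, 1:94]
  grad <- sqrt(gy[, 2:95]^2 + gx[2:95, ]^2)
  rr <- sqrt(outer((1:96 - 48.5)^2, (1:96 - 48.5)^2, `+`))
  edgeR <- sum(rr * etot) / sum(etot)
  gradR <- sum(rr[2:95, 2:95] * grad) / sum(grad)
  expect_lt(abs(edgeR - gradR), 1.5)
})

test_that("center-surround ON/OFF decompose the unrectified DoG", {
  cs0 <- centerSurround(buildPyramid(matrix(1, 64, 64), 4L), 3L)
  for (k in 1:4) {
    expect_lt(max(cs0$on[[k]]), 1e-9)
    expect_lt(max(cs0$off[[k]]), 1e-9)
  }
  set.seed(41)
  pyr <- buildPyramid(matrix(runif(64 * 64), 64, 64), 4L)
  cs <- centerSurround(pyr, 3L)
  for (k in 1:3) {
    sidx <- seq(k + 1, min(4, k + 6))
    m <- pyramidLevel(pyr, k)
    surr <- Reduce(`+`, lapply(sidx, function(j)
      resizeMap(pyramidLevel(pyr, j), nrow(m), ncol(m)))) / length(sidx)
    expect_equal(cs$on[[k]] - cs$off[[k]], m - surr, tolerance = 1e-12)
    expect_true(all(cs$on[[k]] * cs$off[[k]] == 0))
  }
  d <- discImage(96, radius = 18)
  csd <- centerSurround(buildPyramid(d$map, 4L), 3L)
  expect_true(mean(csd$on[[1]][d$mask]) > 5 * mean(csd$on[[1]][!d$mask]))
  ring <- !d$mask & (sqrt(outer((1:96 - 48.5)^2, (1:96 - 48.5)^2, `+`)) < 28)
  expect_gt(mean(csd$off[[1]][ring]), mean(csd$off[[1]][d$mask]))
})

test_that("border ownership votes point into an isolated bright square", {
  cfg <- protoConfig()
  # 6-px square: at level 1 the object matches the annulus/surround scale,
  # where ownership is resolved (larger objects resolve at coarser levels)
  m <- matrix(0, 96, 96); m[46:51, 46:51] <- 1
  pyr <- buildPyramid(m, 5L)
  edges <- edgeResponses(pyr, cfg)
  cs <- centerSurround(pyr, 3L)
  bo <- borderOwnership(edges, cs, cfg)
  # left vertical edge, midpoint (48, 43): side1 of theta=0 points toward +x
  # (into the square); side2 away from it
  expect_gt(bo[["0"]]$side1[[1]][48, 46], bo[["0"]]$side2[[1]][48, 46])
  # right vertical edge: inward is -x, i.e. side2
  expect_gt(bo[["0"]]$side2[[1]][48, 51], bo[["0"]]$side1[[1]][48, 51])
  # top horizontal edge: inward is +y = side1 of theta=90
  expect_gt(bo[["90"]]$side1[[1]][46, 48], bo[["90"]]$side2[[1]][46, 48])
  expect_gt(bo[["90"]]$side2[[1]][51, 48], bo[["90"]]$side1[[1]][51, 48])

  blank <- buildPyramid(matrix(0, 96, 96), 4L)
  bo0 <- borderOwnership(edgeResponses(blank, cfg), centerSurround(blank, 3L), cfg)
  for (th in names(bo0)) {
    expect_lt(max(bo0[[th]]$side1[[1]]), 1e-12)
    expect_lt(max(bo0[[th]]$side2[[1]]), 1e-12)
  }
})

test_that("grouping activity peaks inside convex figures", {
  # disc at the proto-object scale: the maximum sits at the centre
  d8 <- discImage(96, radius = 5)
  m8 <- groupSumAcc(d8$map)
  am8 <- which(m8 == max(m8), arr.ind = TRUE)[1, ]
  expect_lt(sqrt(sum((am8 - d8$center)^2)), 2.5)  # within radius/2
  # larger disc: annular votes peak nearer the border but stay inside
  d <- discImage(96, radius = 16)
  m <- groupSumAcc(d$map)
  am <- which(m == max(m), arr.ind = TRUE)[1, ]
  expect_lt(sqrt(sum((am - d$center)^2)), 16)  # inside the figure
  blank <- groupPyramid(buildPyramid(matrix(0.5, 96, 96), 4L), protoConfig())
  expect_lt(max(blank[[1]]), 1e-9)
})

test_that("grouping is photometrically symmetric and translation equivariant", {
  g1 <- groupSumAcc(discImage(96, center = c(44, 50), radius = 5)$map)
  g2 <- groupSumAcc(discImage(96, center = c(44, 50), radius = 5, neg = TRUE)$map)
  a1 <- which(g1 == max(g1), arr.ind = TRUE)[1, ]
  a2 <- which(g2 == max(g2), arr.ind = TRUE)[1, ]
  expect_lte(max(abs(a1 - a2)), 2)

  shift <- c(7, -5)
  g3 <- groupSumAcc(discImage(96, center = c(44 + shift[1], 50 + shift[2]),
                           radius = 5)$map)
  a3 <- which(g3 == max(g3), arr.ind = TRUE)[1, ]
  expect_lte(max(abs(a3 - (a1 + shift))), 1)
})

test_that("span clipping warns when requested", {
  pyr <- buildPyramid(matrix(runif(64 * 64), 64, 64), 3L)
  expect_warning(centerSurround(pyr, 5L, warn = TRUE), "clipped")
})
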