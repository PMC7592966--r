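test_that("initPhi is a signed exact distance recovering the mask by sign", {
  m <- diskMask(64, 10, c(32, 32))
  st <- initPhi(m)
  # distance-transform oracle: EBImage::distmap computes the same distances,
  # offset by the half pixel that centers the interface between pixels
  din <- EBImage::distmap(m)
  dout <- EBImage::distmap(1 - m)
  expect_equal(st@phi[m == 1], -(din[m == 1] - 0.5))
  expect_equal(st@phi[m == 0], dout[m == 0] - 0.5)
  expect_equal(st@phi[32, 32], -10, tolerance = 0.5)
  expect_identical((st@phi < 0) * 1L, m)
  expect_error(initPhi(matrix(0L, 8, 8)), class = "hepasegNothingToRefine")
})

test_that("Otsu equals exhaustive between-class-variance search", {
  brute <- function(img, nbins = 256L) {
    v <- as.numeric(img)
    lo <- min(v); hi <- max(v)
    bin <- pmin(floor((v - lo) / (hi - lo) * nbins) + 1L, nbins)
    centers <- lo + (seq_len(nbins) - 0.5) * (hi - lo) / nbins
    best <- -Inf; bk <- NA
    for (k in seq_len(nbins - 1L)) {
      c0 <- bin <= k
      if (!any(c0) || all(c0)) next
      w0 <- mean(c0)
      sb <- w0 * (1 - w0) *
        (mean(centers[bin][c0]) - mean(centers[bin][!c0]))^2
      if (sb > best + 1e-12) { best <- sb; bk <- k }
    }
    lo + bk * (hi - lo) / nbins
  }
  for (s in 1:25) {
    set.seed(s)
    img <- matrix(runif(64 * 64)^sample(1:3, 1), 64, 64)
    expect_equal(otsuThreshold(img), brute(img))
  }
  bimodal <- matrix(c(rep(0.2, 200), rep(0.8, 200)), 20, 20)
  t <- otsuThreshold(bimodal)
  expect_true(t > 0.2 && t < 0.8)
  expect_error(otsuThreshold(matrix(1, 5, 5)),
               class = "hepasegDegenerateInput")
})

test_that("local region statistics recover constant phases and flag empty sides", {
  m <- diskMask(64, 15, c(32, 32))
  img <- ifelse(m == 1, 10, 20)
  st <- initPhi(m)
  bd <- localRegionStats(img, st, c(32, 47), r = 5)  # on the boundary
  expect_equal(bd$u, 10)
  expect_equal(bd$v, 20)
  ctr <- localRegionStats(img, st, c(32, 32), r = 5)  # ball fully inside
  expect_false(ctr$vDefined)
  expect_equal(ctr$force, 0)
  # noisy phase: interior mean concentrates around 10
  set.seed(6)
  noisy <- img + matrix(rnorm(64 * 64, 0, 1), 64, 64)
  nb <- localRegionStats(noisy, st, c(32, 47), r = 5)
  expect_lt(abs(nb$u - 10), 3 / sqrt(20))
})

test_that("Chan-Vese energy is zero at a perfect piecewise-constant fit", {
  m <- diskMask(64, 15, c(32, 32))
  img <- ifelse(m == 1, 0.3, 0.7)
  st <- initPhi(m)
  expect_equal(chanVeseEnergy(img, st, mu = 0), 0)
  displaced <- initPhi(diskMask(64, 15, c(40, 40)))
  expect_gt(chanVeseEnergy(img, displaced, mu = 0), 0)
  # mu adds exactly mu x perimeter estimate for fixed phi
  e0 <- chanVeseEnergy(img, st, mu = 0)
  e1 <- chanVeseEnergy(img, st, mu = 1)
  e2 <- chanVeseEnergy(img, st, mu = 2)
  expect_gt(e1 - e0, 0)
  expect_equal(e2 - e0, 2 * (e1 - e0))
  # the perimeter estimate is near the true circle length 2*pi*15
  expect_lt(abs((e1 - e0) - 2 * pi * 15) / (2 * pi * 15), 0.15)
})

test_that("evolution recovers the disk boundary from perturbed starts", {
  fx <- twoPhaseDisk(n = 96, r = 28, seed = 12)
  p <- levelSetParams(maxIters = 200L)
  for (r in c(-4, 0, 4)) {
    init <- if (r > 0) dilateMask(fx$truth, r)
    else if (r < 0) erodeMask(fx$truth, -r) else fx$truth
    out <- evolveContour(fx$img, init, p)
    expect_true(all(out %in% c(0L, 1L)))
    expect_equal(dim(out), dim(fx$img))
    expect_gte(dice2d(out, fx$truth), 0.98)
  }
  expect_error(evolveContour(fx$img, matrix(0L, 96, 96), p),
               class = "hepasegNothingToRefine")
})

test_that("the intensity gate keeps out-of-range pixels in the exterior", {
  fx <- twoPhaseDisk(n = 96, r = 28, seed = 14)
  # inside phase is 0.3: gating to [0, 0.5] still recovers the disk
  out <- evolveContour(fx$img, dilateMask(fx$truth, 4),
                       levelSetParams(maxIters = 200L), gate = c(0, 0.5))
  expect_gte(dice2d(out, fx$truth), 0.98)
})
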