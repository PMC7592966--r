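test_that("HU windowing maps the -50..250 window onto [0,1]", {
  w <- windowSpec()
  expect_equal(huWindow(-1000, w), 0)    # air
  expect_equal(huWindow(400, w), 1)      # bone
  expect_equal(huWindow(100, w), 0.5)    # (100 - (-50)) / 300
  expect_equal(huWindow(-50, w), 0)
  expect_equal(huWindow(250, w), 1)
  expect_error(windowSpec(lo = 10, hi = 10), "lo < hi")
})

test_that("HU windowing is monotone and idempotent on re-expressed data", {
  set.seed(1)
  x <- sort(runif(500, -1200, 600))
  y <- huWindow(x)
  expect_true(all(diff(y) >= 0))
  expect_true(all(y >= 0 & y <= 1))
  # windowed values re-expressed in HU window back to themselves
  hu <- y * 300 - 50
  expect_equal(huWindow(hu), y, tolerance = 1e-12)
  vol <- ctVolume(array(runif(8^3, -200, 400), c(8, 8, 8)))
  expect_s4_class(huWindow(vol), "CTVolume")
})

test_that("median filter matches small hand-computed cases", {
  expect_equal(medianFilter2D(matrix(5, 10, 10), 3), matrix(5, 10, 10))
  p <- matrix(1:9, 3, 3, byrow = TRUE)
  expect_equal(medianFilter2D(p, 3)[2, 2], 5)
  z <- matrix(0, 21, 21)
  z[11, 11] <- 1000
  expect_equal(max(abs(medianFilter2D(z, 3))), 0)
  expect_error(medianFilter2D(z, 4), class = "hepasegContractError")
})

test_that("median filter output stays inside the local value set", {
  set.seed(2)
  x <- matrix(sample(c(0, 0.5, 1), 400, replace = TRUE), 20, 20)
  y <- medianFilter2D(x, 3)
  expect_true(all(y %in% c(0, 0.5, 1)))
  expect_gte(min(y), min(x))
  expect_lte(max(y), max(x))
})

test_that("edge-enhancing diffusion denoises phases, keeps contrast and mean", {
  fx <- twoPhaseVolume()
  img <- fx$vol@voxels
  out <- eedFilter(fx$vol)@voxels
  # mean conservation and discrete extremum principle
  expect_lt(abs(mean(out) - mean(img)) / abs(mean(img)), 0.001)
  expect_lte(max(out), max(img) + 1e-6)
  expect_gte(min(out), min(img) - 1e-6)
  inE <- erode3d(fx$truth, 3)
  outE <- erode3d(1 - fx$truth, 3)
  expect_lte(var(out[inE]), 0.5 * var(img[inE]))
  expect_lte(var(out[outE]), 0.5 * var(img[outE]))
  c0 <- abs(mean(img[inE]) - mean(img[outE]))
  c1 <- abs(mean(out[inE]) - mean(out[outE]))
  expect_gte(c1, 0.9 * c0)
  # Fisher separability of the two phases strictly increases
  f0 <- c0^2 / (var(img[inE]) + var(img[outE]))
  f1 <- c1^2 / (var(out[inE]) + var(out[outE]))
  expect_gt(f1, f0)
})

test_that("diffusion leaves constant volumes unchanged and rejects unstable steps", {
  cv <- ctVolume(array(0.4, c(12, 12, 12)))
  expect_equal(eedFilter(cv)@voxels, cv@voxels, tolerance = 1e-12)
  expect_error(eedFilter(cv, eedParams(tau = 0.4)),
               class = "hepasegContractError")
  expect_error(eedFilter(ctVolume(array(0.5, c(4, 4, 4)))),
               class = "hepasegContractError")
})

test_that("liver ROI crop boxes, masking and inversion behave", {
  vol <- ctVolume(array(1, c(32, 32, 32)))
  lv <- array(0L, c(32, 32, 32))
  lv[11:21, 11:21, 11:21] <- 1L
  cr <- cropLiverROI(vol, binaryMask(lv), margin = 2L)
  expect_identical(cr$record@cropBox,
                   cbind(rep(9L, 3), rep(23L, 3)))
  # voxels inside the box but outside the mask are zeroed
  expect_equal(cr$roi@voxels[1, 1, 1], 0)
  expect_equal(cr$roi@voxels[8, 8, 8], 1)  # inside mask (global 16,16,16)
  # crop then inverse-crop is the identity on the uncropped region
  back <- uncropToGrid(cr$roi@voxels, cr$record)
  expect_equal(back[9:23, 9:23, 9:23], cr$roi@voxels)
  expect_error(cropLiverROI(vol, binaryMask(array(0L, c(32, 32, 32)))),
               class = "hepasegNoLiver")
})
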