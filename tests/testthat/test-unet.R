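test_that("default architecture audits to 19 convolutional layers", {
  expect_identical(countConvLayers(unetConfig()), 19L)
  m1 <- buildUNet(unetConfig(), seed = 1)
  m2 <- buildUNet(unetConfig(), seed = 2)
  # parameter count is an architectural constant across initializations
  expect_identical(vapply(m1@params, length, integer(1)),
                   vapply(m2@params, length, integer(1)))
  expect_identical(buildUNet(unetConfig(), seed = 1)@params, m1@params)
})

test_that("network output is a probability map of the input size", {
  cfg <- unetConfig(inputSize = 32L, depth = 2L, baseFilters = 4L)
  m <- buildUNet(cfg, seed = 5)
  set.seed(1)
  p <- hepaseg:::unetForward(m, matrix(runif(32 * 32), 32, 32))$prob
  expect_equal(dim(p), c(32L, 32L, 1L, 1L))
  expect_true(all(p >= 0 & p <= 1))
  expect_error(unetConfig(inputSize = 100L, depth = 3L),
               "divisible")
})

test_that("soft-Dice loss matches its closed forms and the Dice identity", {
  t100 <- matrix(0, 32, 32)
  t100[1:10, 1:10] <- 1
  expect_equal(softDiceLoss(matrix(0, 32, 32), t100, eps = 1),
               1 - 1 / 101)
  half <- matrix(0, 32, 32)
  half[, 1:16] <- 1
  expect_equal(softDiceLoss(matrix(0.5, 32, 32), half, eps = 0), 0.5)
  expect_equal(softDiceLoss(half, half, eps = 1e-12), 0, tolerance = 1e-9)
  # 1 - soft dice equals the Dice coefficient on binary inputs as eps -> 0
  set.seed(4)
  for (i in 1:5) {
    a <- matrix(rbinom(256, 1, 0.3), 16, 16)
    b <- matrix(rbinom(256, 1, 0.3), 16, 16)
    expect_equal(1 - softDiceLoss(a, b, eps = 1e-9),
                 dice2d(a, b), tolerance = 1e-6)
  }
  expect_error(softDiceLoss(matrix(0, 2, 2), matrix(0, 3, 3)),
               class = "hepasegContractError")
})

test_that("backpropagated gradients match finite differences", {
  cfg <- unetConfig(inputSize = 16L, depth = 2L, baseFilters = 2L,
                    dropoutRate = 0)
  model <- buildUNet(cfg, seed = 42)
  set.seed(3)
  x <- array(runif(16 * 16 * 2), dim = c(16, 16, 1, 2))
  y <- array(rbinom(16 * 16 * 2, 1, 0.3), dim = c(16, 16, 1, 2))
  fw <- hepaseg:::unetForward(model, x, training = FALSE, keepCache = TRUE)
  lg <- hepaseg:::softDiceLossGrad(fw$prob, y)
  G <- hepaseg:::unetBackward(model, fw$cache, lg$grad)
  lossAt <- function(P) {
    m <- model
    m@params <- P
    softDiceLoss(hepaseg:::unetForward(m, x, FALSE, FALSE)$prob, y)
  }
  set.seed(9)
  rel <- c()
  h <- 1e-6
  for (nm in names(model@params)) {
    P <- model@params
    for (t in sample(length(P[[nm]]), min(3, length(P[[nm]])))) {
      P2 <- P; P2[[nm]][t] <- P2[[nm]][t] + h
      P3 <- P; P3[[nm]][t] <- P3[[nm]][t] - h
      num <- (lossAt(P2) - lossAt(P3)) / (2 * h)
      rel <- c(rel, abs(num - G[[nm]][t]) /
                 max(1e-8, abs(num) + abs(G[[nm]][t])))
    }
  }
  # a handful of checks may straddle a ReLU kink or max-pool tie under
  # finite differencing; systematic backprop errors would fail everywhere
  expect_lt(median(rel), 1e-5)
  expect_gte(mean(rel < 1e-3), 0.9)
  expect_lt(max(rel), 0.25)
})

test_that("training-slice selection follows the exclusion rules", {
  v <- array(rnorm(32 * 32 * 30, 60, 20), c(32, 32, 30))
  liver <- array(0L, c(32, 32, 30))
  liver[10:24, 10:24, 10:20] <- 1L   # liver on slices 10..20 only
  tumor <- array(0L, c(32, 32, 30))
  vols <- list(ctVolume(v))
  ds <- selectTrainingSlices(vols, list(binaryMask(liver)), stage = "liver",
                             inputSize = 16L)
  expect_equal(dim(ds@x)[4], 11L)
  expect_true(all(apply(ds@y, 4, sum) > 0))
  # a volume with an empty tumor mask contributes no tumor slices
  expect_error(
    selectTrainingSlices(vols, list(binaryMask(liver)),
                         list(binaryMask(tumor)), stage = "tumor",
                         inputSize = 16L),
    class = "hepasegEmptyDataset")
  expect_error(
    selectTrainingSlices(vols, list(binaryMask(tumor)), stage = "liver",
                         inputSize = 16L),
    class = "hepasegEmptyDataset")
})

test_that("zero epochs is a no-op and the LR schedule is multiplicative", {
  set.seed(2)
  x <- array(runif(16 * 16 * 8), c(16, 16, 1, 8))
  y <- array(rbinom(16 * 16 * 8, 1, 0.2), c(16, 16, 1, 8))
  ds <- new("SliceDataset", x = x, y = y, stage = "liver",
            provenance = data.frame(case = 1:8, slice = 1:8))
  m <- buildUNet(unetConfig(inputSize = 16L, depth = 2L, baseFilters = 2L),
                 seed = 1)
  tr0 <- trainUNet(m, ds, trainingConfig(epochs = 0L))
  expect_identical(tr0$model@params, m@params)
  expect_equal(nrow(tr0$history), 0L)
  tr <- trainUNet(m, ds, trainingConfig(epochs = 10L, lrPatience = 1L,
                                        seed = 3L,
                                        validationFraction = 0.25))
  expect_equal(nrow(tr$history), 10L)
  # every learning rate is lr0 * factor^k for integer k >= 0, non-increasing
  ks <- log10(0.001 / tr$history$lr)
  expect_true(all(abs(ks - round(ks)) < 1e-9))
  expect_true(all(diff(tr$history$lr) <= 1e-15))
})

test_that("prediction is deterministic and slice-count preserving", {
  cfg <- unetConfig(inputSize = 16L, depth = 2L, baseFilters = 2L)
  m <- buildUNet(cfg, seed = 7)
  m@trained <- TRUE
  sl <- matrix(runif(24 * 24), 24, 24)
  vol <- ctVolume(array(rep(sl, 5), c(24, 24, 5)))
  maps <- predictVolume(m, vol)
  expect_length(maps, 5)
  expect_true(all(vapply(maps, function(p) all(p >= 0 & p <= 1),
                         logical(1))))
  # identical input slices give identical maps
  expect_equal(maps[[1]], maps[[4]])
  expect_equal(predictVolume(m, vol), maps)
})

test_that("binarize thresholds with the >= tie rule and validates its cut", {
  maps <- list(matrix(0.6, 8, 8), matrix(0.5, 8, 8), matrix(0.49, 8, 8))
  b <- binarizeMaps(maps, 0.5)
  expect_equal(dim(b), c(8L, 8L, 3L))
  expect_true(all(b[, , 1] == 1))
  expect_true(all(b[, , 2] == 1))  # p == threshold counts as foreground
  expect_true(all(b[, , 3] == 0))
  expect_error(binarizeMaps(maps, 1.5), class = "hepasegContractError")
})
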