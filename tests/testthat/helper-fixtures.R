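# Fixtures built in code; no binary data.

# centered disk mask
diskMask <- function(n = 128, r = 40, center = c(n / 2, n / 2)) {
  i <- matrix(seq_len(n), n, n)
  j <- t(i)
  m <- matrix(0L, n, n)
  m[(i - center[1])^2 + (j - center[2])^2 <= r^2] <- 1L
  m
}

# noisy two-phase disk: inside 0.3, outside 0.7, additive Gaussian noise
twoPhaseDisk <- function(n = 128, r = 40, sigma = 0.05, seed = 11) {
  set.seed(seed)
  truth <- diskMask(n, r)
  img <- ifelse(truth == 1, 0.3, 0.7) + matrix(rnorm(n * n, 0, sigma), n, n)
  list(img = img, truth = truth)
}

# morphology through the signed distance of initPhi
dilateMask <- function(m, r) {
  phi <- initPhi(m)@phi
  (phi <= r) * 1L
}
erodeMask <- function(m, r) {
  phi <- initPhi(m)@phi
  (phi <= -r) * 1L
}

dice2d <- function(a, b) {
  diceCoefficient(array(a, c(dim(a), 1)), array(b, c(dim(b), 1)))
}

# two-phase 3D ellipsoid fixture for the diffusion tests
twoPhaseVolume <- function(dims = c(48, 48, 24), sigma = 0.05, seed = 21) {
  set.seed(seed)
  truth <- array(0L, dims)
  for (k in seq_len(dims[3]))
    for (i in seq_len(dims[1]))
      for (j in seq_len(dims[2]))
        if (((i - dims[1] / 2) / (0.3 * dims[1]))^2 +
            ((j - dims[2] / 2) / (0.3 * dims[2]))^2 +
            ((k - dims[3] / 2) / (0.3 * dims[3]))^2 <= 1)
          truth[i, j, k] <- 1L
  img <- ifelse(truth == 1, 0.3, 0.7) +
    array(rnorm(prod(dims), 0, sigma), dims)
  list(vol = ctVolume(img, spacing = c(1.5, 1.5, 2.5)), truth = truth)
}

# erode a 3D mask by r (in-plane pixel metric, slice axis spacing-weighted)
erode3d <- function(m, r, hz = 2.5 / 1.5) {
  d <- hepaseg:::cpp_edt(array(as.integer(m == 0), dim(m)), c(1, 1, hz))
  m == 1 & d > r
}

# a small trained cascade, built once per test run and reused
tinyStudyEnv <- new.env()
getTinyStudy <- function() {
  if (is.null(tinyStudyEnv$study)) {
    tinyStudyEnv$study <- runPhantomStudy(
      nTrain = 6L, nTest = 2L, seed = 13L, netSize = 32L, liverDepth = 3L,
      tumorDepth = 2L, baseFilters = 8L, tc = trainingConfig(epochs = 6L))
  }
  tinyStudyEnv$study
}
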