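# User-facing constructors. Validity methods in AllClasses.R do the checking.

#' Construct a CT volume
#' @param voxels 3D numeric array in HU.
#' @param spacing voxel spacing in mm (length 3, positive).
#' @param header optional NIfTI header carried over from a source file.
#' @return a [CTVolume-class].
#' @export
ctVolume <- function(voxels, spacing = c(1, 1, 1), header = NULL) {
  new("CTVolume", voxels = voxels, spacing = as.numeric(spacing),
      axialAxis = 3L, header = header)
}

#' Construct a binary mask
#' @param voxels 3D array coercible to \{0,1\} integers.
#' @param spacing voxel spacing in mm.
#' @return a [BinaryMask-class].
#' @export
binaryMask <- function(voxels, spacing = c(1, 1, 1)) {
  v <- array(as.integer(voxels), dim = dim(voxels))
  new("BinaryMask", voxels = v, spacing = as.numeric(spacing),
      axialAxis = 3L)
}

#' Construct an HU window
#' @param lo,hi window bounds in HU (defaults -50 and 250).
#' @param rescale map the window onto \[0,1\].
#' @return a [WindowSpec-class].
#' @export
windowSpec <- function(lo = -50, hi = 250, rescale = TRUE) {
  new("WindowSpec", lo = lo, hi = hi, rescale = rescale)
}

#' Construct edge-enhancing diffusion parameters
#' @param sigma,rho,lambda,tau,nSteps,m,Cm see [EEDParams-class].
#' @return an [EEDParams-class].
#' @export
eedParams <- function(sigma = 1.0, rho = 2.0, lambda = 0.05, tau = 0.1,
                      nSteps = 10L, m = 4, Cm = 3.31488) {
  new("EEDParams", sigma = sigma, rho = rho, lambda = lambda, tau = tau,
      nSteps = as.integer(nSteps), m = m, Cm = Cm)
}

#' Construct level-set parameters
#' @param radius,mu,dt,maxIters,reinitEvery,tol,epsilon see
#'   [LevelSetParams-class].
#' @return a [LevelSetParams-class].
#' @export
levelSetParams <- function(radius = 9, mu = 0.2, dt = 0.45, maxIters = 200L,
                           reinitEvery = 20L, tol = 1e-3, epsilon = 1.5) {
  new("LevelSetParams", radius = radius, mu = mu, dt = dt,
      maxIters = as.integer(maxIters), reinitEvery = as.integer(reinitEvery),
      tol = tol, epsilon = epsilon)
}

#' Construct a U-Net configuration
#' @param inputSize,depth,baseFilters,convPerBlock,dropoutRate see
#'   [UNetConfig-class].
#' @return a [UNetConfig-class].
#' @export
unetConfig <- function(inputSize = 256L, depth = 4L, baseFilters = 32L,
                       convPerBlock = 2L, dropoutRate = 0.5) {
  new("UNetConfig", inputSize = as.integer(inputSize),
      depth = as.integer(depth), baseFilters = as.integer(baseFilters),
      convPerBlock = as.integer(convPerBlock), dropoutRate = dropoutRate)
}

#' Construct a training configuration
#' @param epochs,batchSize,lr0,lrFactor,lrPatience,seed,validationFraction
#'   see [TrainingConfig-class].
#' @return a [TrainingConfig-class].
#' @export
trainingConfig <- function(epochs = 20L, batchSize = 32L, lr0 = 0.001,
                           lrFactor = 0.1, lrPatience = 5L, seed = 1L,
                           validationFraction = 0.1) {
  new("TrainingConfig", epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), lr0 = lr0, lrFactor = lrFactor,
      lrPatience = as.integer(lrPatience), seed = as.integer(seed),
      validationFraction = validationFraction)
}

#' Construct a phantom specification
#' @param ... slot values overriding the defaults of [PhantomSpec-class].
#' @param seed RNG seed.
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(..., seed = 1L) {
  args <- list(...)
  for (nm in c("dim", "tumorCount"))
    if (!is.null(args[[nm]])) args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list("PhantomSpec", seed = as.integer(seed)), args))
}

#' Construct a pipeline configuration
#' @param window HU window ([WindowSpec-class]).
#' @param medianKernel odd kernel of the liver-stage median filter.
#' @param eed diffusion parameters for the tumor stage.
#' @param liverNet,tumorNet trained [UNetModel-class] handles (may be NULL
#'   until training).
#' @param liverLS,tumorLS level-set parameters per stage.
#' @param threshold probability cut in (0, 1).
#' @param roiMargin liver-box dilation in px.
#' @param useLevelSetLiver,useLevelSetTumor ablation switches.
#' @param useOtsuGate couple the Otsu intensity gate into the level set.
#' @return a [PipelineConfig-class].
#' @export
pipelineConfig <- function(window = windowSpec(), medianKernel = 3L,
                           eed = eedParams(), liverNet = NULL,
                           tumorNet = NULL,
                           liverLS = levelSetParams(maxIters = 200L),
                           tumorLS = levelSetParams(maxIters = 100L),
                           threshold = 0.5, roiMargin = 5L,
                           useLevelSetLiver = TRUE, useLevelSetTumor = TRUE,
                           useOtsuGate = TRUE) {
  new("PipelineConfig", window = window,
      medianKernel = as.integer(medianKernel), eed = eed,
      liverNet = liverNet, tumorNet = tumorNet, liverLS = liverLS,
      tumorLS = tumorLS, threshold = threshold,
      roiMargin = as.integer(roiMargin),
      useLevelSetLiver = useLevelSetLiver,
      useLevelSetTumor = useLevelSetTumor, useOtsuGate = useOtsuGate)
}
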