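#' @useDynLib hepaseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats rnorm runif sd var
#' @importFrom utils head write.csv
NULL

# ---------------------------------------------------------------------------
# Data containers
# ---------------------------------------------------------------------------

#' CT volume in Hounsfield units
#'
#' A 3D scalar grid with voxel spacing. The third array axis is the axial
#' (slice) axis by convention; indices are 0-based in the documentation and
#' 1-based in R code, with (row, column) = (y, x) within a slice.
#'
#' @slot voxels 3D numeric array of intensities (HU, or \[0,1\] after
#'   windowing).
#' @slot spacing voxel spacing in mm along the three array axes, all > 0.
#' @slot axialAxis index of the slice axis (always 3 here).
#' @slot header NIfTI header of the source file (or `NULL` for synthetic
#'   volumes), kept so results can be written aligned with the input.
#' @export
setClass("CTVolume",
  representation(voxels = "array", spacing = "numeric",
                 axialAxis = "integer", header = "ANY"),
  prototype(spacing = c(1, 1, 1), axialAxis = 3L, header = NULL))

setValidity("CTVolume", function(object) {
  d <- dim(object@voxels)
  if (length(d) != 3L) return("voxels must be a 3D array")
  if (any(d < 1L)) return("voxel grid must be non-empty")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be three strictly positive numbers")
  if (any(!is.finite(object@voxels))) return("voxel values must be finite")
  if (object@axialAxis != 3L) return("axialAxis must be 3")
  TRUE
})

#' Binary mask on a CT grid
#'
#' Per-voxel \{0,1\} labels sharing the grid of a parent [CTVolume-class].
#'
#' @slot voxels 3D integer array with values in \{0,1\}.
#' @slot spacing voxel spacing in mm.
#' @slot axialAxis index of the slice axis.
#' @export
setClass("BinaryMask",
  representation(voxels = "array", spacing = "numeric",
                 axialAxis = "integer"),
  prototype(spacing = c(1, 1, 1), axialAxis = 3L))

setValidity("BinaryMask", function(object) {
  d <- dim(object@voxels)
  if (length(d) != 3L) return("voxels must be a 3D array")
  if (!all(object@voxels %in% c(0L, 1L)))
    return("mask values must be exactly 0 or 1")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be three strictly positive numbers")
  TRUE
})

#' One axial slice of a volume
#'
#' @slot pixels 2D numeric matrix.
#' @slot volumeId identifier of the parent volume.
#' @slot index 1-based slice index along the axial axis.
#' @export
setClass("SliceImage",
  representation(pixels = "matrix", volumeId = "character",
                 index = "integer"),
  prototype(volumeId = NA_character_, index = NA_integer_))

#' Record of a resize/crop transform, sufficient to invert it
#'
#' @slot sourceDim dimensions before the transform.
#' @slot targetDim dimensions after the transform.
#' @slot order interpolation used: "bilinear" or "nearest".
#' @slot cropBox 2-column integer matrix of per-axis (first, last) indices of
#'   the crop, or a 0-row matrix when no crop was applied.
#' @export
setClass("ResampleRecord",
  representation(sourceDim = "integer", targetDim = "integer",
                 order = "character", cropBox = "matrix"),
  prototype(order = "bilinear", cropBox = matrix(integer(), 0, 2)))

#' State of a 2D level-set contour
#'
#' @slot phi signed embedding, negative inside the contour.
#' @slot iteration number of evolution iterations performed.
#' @slot energy last global Chan-Vese energy value (NA until evaluated).
#' @export
setClass("LevelSetState",
  representation(phi = "matrix", iteration = "integer", energy = "numeric"),
  prototype(iteration = 0L, energy = NA_real_))

#' Paired slices and target masks for network training
#'
#' Every target slice contains at least one foreground pixel; slices with an
#' empty target are excluded from training, and for the tumor stage whole
#' volumes without any tumor annotation are excluded.
#'
#' @slot x inputs, array (h, w, 1, n).
#' @slot y targets, array (h, w, 1, n) with values in \{0,1\}.
#' @slot stage "liver" or "tumor".
#' @slot provenance data.frame with one row per pair (case, slice index).
#' @export
setClass("SliceDataset",
  representation(x = "array", y = "array", stage = "character",
                 provenance = "data.frame"))

#' Output of the two-stage segmentation pipeline
#'
#' @slot liver refined liver mask on the original grid.
#' @slot tumor refined tumor mask (subset of liver) on the original grid.
#' @slot liverUNet,tumorUNet the network-only masks before level-set
#'   refinement, kept for ablation.
#' @slot provenance list of every parameter actually used.
#' @export
setClass("SegmentationResult",
  representation(liver = "BinaryMask", tumor = "BinaryMask",
                 liverUNet = "BinaryMask", tumorUNet = "BinaryMask",
                 provenance = "list"))

setValidity("SegmentationResult", function(object) {
  dl <- dim(object@liver@voxels)
  for (s in c("tumor", "liverUNet", "tumorUNet"))
    if (!identical(dim(slot(object, s)@voxels), dl))
      return("all masks must share one grid")
  if (any(object@tumor@voxels > object@liver@voxels))
    return("tumor mask must be a voxelwise subset of the liver mask")
  TRUE
})

# ---------------------------------------------------------------------------
# Parameter classes
# ---------------------------------------------------------------------------

#' Hounsfield-unit window
#'
#' Intensities are clipped to \[lo, hi\] and mapped onto \[0, 1\]. The default
#' window of -50 to 250 HU spans the liver and tumor intensity range while
#' excluding air and compact bone.
#'
#' @slot lo,hi window bounds in HU, lo < hi.
#' @slot rescale map \[lo, hi\] onto \[0, 1\] (always recommended).
#' @export
setClass("WindowSpec",
  representation(lo = "numeric", hi = "numeric", rescale = "logical"),
  prototype(lo = -50, hi = 250, rescale = TRUE))

setValidity("WindowSpec", function(object) {
  if (!(object@lo < object@hi)) return("window requires lo < hi")
  TRUE
})

#' Edge-enhancing diffusion parameters
#'
#' Explicit-scheme anisotropic diffusion steered by a tensor whose eigenvalue
#' along the regularized gradient is the Weickert diffusivity
#' g(s) = 1 - exp(-Cm / (s/lambda^2)^m), with unit diffusion on the
#' orthogonal complement. The time step must satisfy the explicit stability
#' bound tau <= 1 / (2 * (1/hx^2 + 1/hy^2 + 1/hz^2)) with in-plane pixel
#' units hx = hy = 1 and hz the relative slice spacing.
#'
#' @slot sigma Gaussian pre-smoothing scale in px.
#' @slot rho tensor integration scale in px.
#' @slot lambda contrast parameter in windowed-intensity units.
#' @slot tau explicit time step.
#' @slot nSteps number of diffusion iterations.
#' @slot m,Cm diffusivity exponent and normalizing constant.
#' @export
setClass("EEDParams",
  representation(sigma = "numeric", rho = "numeric", lambda = "numeric",
                 tau = "numeric", nSteps = "integer", m = "numeric",
                 Cm = "numeric"),
  prototype(sigma = 1.0, rho = 2.0, lambda = 0.05, tau = 0.1, nSteps = 10L,
            m = 4, Cm = 3.31488))

setValidity("EEDParams", function(object) {
  if (object@lambda <= 0) return("lambda must be > 0")
  if (object@nSteps < 1L) return("nSteps must be >= 1")
  if (object@tau <= 0) return("tau must be > 0")
  TRUE
})

#' Localized level-set parameters
#'
#' @slot radius localization ball radius in px (also the narrow-band width).
#' @slot mu curve-length regularization weight.
#' @slot dt CFL number: the largest per-iteration update of phi, in px.
#' @slot maxIters iteration cap.
#' @slot reinitEvery iterations between signed-distance reinitializations.
#' @slot tol mean |dphi| over the band declaring convergence.
#' @slot epsilon half-width of the smoothed Heaviside/Dirac in px.
#' @export
setClass("LevelSetParams",
  representation(radius = "numeric", mu = "numeric", dt = "numeric",
                 maxIters = "integer", reinitEvery = "integer",
                 tol = "numeric", epsilon = "numeric"),
  prototype(radius = 9, mu = 0.2, dt = 0.45, maxIters = 200L,
            reinitEvery = 20L, tol = 1e-3, epsilon = 1.5))

setValidity("LevelSetParams", function(object) {
  if (object@radius < 2) return("radius must be >= 2")
  if (object@dt <= 0) return("dt must be > 0")
  if (object@mu < 0) return("mu must be >= 0")
  if (object@maxIters < 1L) return("maxIters must be >= 1")
  TRUE
})

#' U-Net architecture configuration
#'
#' The default configuration (256x256 input, depth 4, two convolutions per
#' contracting block, one per expanding block after each transposed
#' convolution, one 1x1 sigmoid output convolution) comprises exactly 19
#' convolutional layers.
#'
#' @slot inputSize side length of the square input slice.
#' @slot depth number of pooling levels.
#' @slot baseFilters channels at the first level; doubled per level.
#' @slot convPerBlock convolutions per contracting block.
#' @slot dropoutRate dropout applied before the output layer (training only).
#' @export
setClass("UNetConfig",
  representation(inputSize = "integer", depth = "integer",
                 baseFilters = "integer", convPerBlock = "integer",
                 dropoutRate = "numeric"),
  prototype(inputSize = 256L, depth = 4L, baseFilters = 32L,
            convPerBlock = 2L, dropoutRate = 0.5))

setValidity("UNetConfig", function(object) {
  if (object@inputSize %% (2L^object@depth) != 0L)
    return("inputSize must be divisible by 2^depth")
  if (object@inputSize < 8L) return("inputSize must be >= 8")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    return("dropoutRate must be in [0, 1)")
  TRUE
})

#' Network training configuration
#'
#' Adam optimization of the soft-Dice loss; the learning rate is multiplied
#' by `lrFactor` whenever the monitored loss fails to improve for
#' `lrPatience` epochs (reduce-on-plateau), so after k reductions
#' lr = lr0 * lrFactor^k.
#'
#' @slot epochs number of passes over the training pairs.
#' @slot batchSize mini-batch size.
#' @slot lr0 initial learning rate.
#' @slot lrFactor multiplicative reduction factor.
#' @slot lrPatience epochs without improvement before a reduction.
#' @slot seed RNG seed governing weight initialization and shuffling.
#' @slot validationFraction fraction of pairs held out for monitoring.
#' @export
setClass("TrainingConfig",
  representation(epochs = "integer", batchSize = "integer", lr0 = "numeric",
                 lrFactor = "numeric", lrPatience = "integer",
                 seed = "integer", validationFraction = "numeric"),
  prototype(epochs = 20L, batchSize = 32L, lr0 = 0.001, lrFactor = 0.1,
            lrPatience = 5L, seed = 1L, validationFraction = 0.1))

setValidity("TrainingConfig", function(object) {
  if (object@epochs < 0L) return("epochs must be >= 0")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (object@lr0 <= 0) return("lr0 must be > 0")
  if (object@validationFraction < 0 || object@validationFraction >= 1)
    return("validationFraction must be in [0, 1)")
  TRUE
})

#' A U-Net model handle
#'
#' @slot config the [UNetConfig-class] the parameters were built for.
#' @slot params named list of weight and bias arrays.
#' @slot stage "liver", "tumor", or "" when unassigned.
#' @slot trained whether [trainUNet()] has updated the parameters.
#' @export
setClass("UNetModel",
  representation(config = "UNetConfig", params = "list", stage = "character",
                 trained = "logical"),
  prototype(stage = "", trained = FALSE))

#' Synthetic abdominal CT phantom specification
#'
#' Describes the intensity regime the segmentation method assumes at
#' portal-venous phase: a bright quasi-ellipsoidal liver (mean 120 HU),
#' darker blob tumors inside it (mean 45 HU), soft tissue near 40 HU, air at
#' -1000 HU, bone near 450 HU, plus additive Gaussian noise. These are
#' synthetic design conventions chosen inside the -50 to 250 HU working
#' window, not measurements.
#'
#' @slot dim grid dimensions.
#' @slot spacing voxel spacing in mm.
#' @slot liverCenter,liverAxes ellipsoid center and semi-axes in voxels
#'   (NA center = drawn from the default placement region).
#' @slot perturbAmp amplitude of the low-frequency radial boundary
#'   perturbation (fraction of the radius).
#' @slot liverHU,liverSD liver parenchyma intensity mean/sd in HU.
#' @slot tumorCount number of tumors (drawn from 0..4 when NA).
#' @slot tumorRadius admissible tumor radius range in px.
#' @slot tumorHU,tumorSD tumor intensity mean/sd in HU.
#' @slot softHU,airHU,boneHU background structure intensities in HU.
#' @slot noiseSD additive Gaussian noise sd in HU.
#' @slot seed RNG seed.
#' @export
setClass("PhantomSpec",
  representation(dim = "integer", spacing = "numeric",
                 liverCenter = "numeric", liverAxes = "numeric",
                 perturbAmp = "numeric", liverHU = "numeric",
                 liverSD = "numeric", tumorCount = "integer",
                 tumorRadius = "numeric", tumorHU = "numeric",
                 tumorSD = "numeric", softHU = "numeric", airHU = "numeric",
                 boneHU = "numeric", noiseSD = "numeric", seed = "integer"),
  prototype(dim = c(128L, 128L, 48L), spacing = c(1.5, 1.5, 2.5),
            liverCenter = c(NA_real_, NA_real_, NA_real_),
            liverAxes = c(NA_real_, NA_real_, NA_real_),
            perturbAmp = 0.08, liverHU = 120, liverSD = 15,
            tumorCount = NA_integer_, tumorRadius = c(4, 14), tumorHU = 45,
            tumorSD = 10, softHU = 40, airHU = -1000, boneHU = 450,
            noiseSD = 10, seed = 1L))

setValidity("PhantomSpec", function(object) {
  if (length(object@dim) != 3L || any(object@dim < 16L))
    return("dim must be three values >= 16")
  if (any(object@spacing <= 0)) return("spacing must be positive")
  if (object@tumorRadius[1] > object@tumorRadius[2])
    return("tumorRadius must be an increasing range")
  if (object@noiseSD < 0) return("noiseSD must be >= 0")
  TRUE
})

#' Configuration of the full cascade
#'
#' @slot window HU window applied to every volume.
#' @slot medianKernel odd kernel size of the liver-stage median filter.
#' @slot eed diffusion parameters for the tumor-stage enhancement.
#' @slot liverNet,tumorNet trained [UNetModel-class] handles.
#' @slot liverLS,tumorLS level-set parameters per stage.
#' @slot threshold probability cut turning maps into masks.
#' @slot roiMargin dilation of the liver bounding box in px.
#' @slot useLevelSetLiver,useLevelSetTumor ablation switches.
#' @slot useOtsuGate couple an Otsu-derived intensity gate into the level
#'   set (liver stage keeps intensities above the threshold, tumor stage
#'   keeps nonzero intensities below it).
#' @export
setClass("PipelineConfig",
  representation(window = "WindowSpec", medianKernel = "integer",
                 eed = "EEDParams", liverNet = "ANY", tumorNet = "ANY",
                 liverLS = "LevelSetParams", tumorLS = "LevelSetParams",
                 threshold = "numeric", roiMargin = "integer",
                 useLevelSetLiver = "logical", useLevelSetTumor = "logical",
                 useOtsuGate = "logical"),
  prototype(medianKernel = 3L, threshold = 0.5, roiMargin = 5L,
            useLevelSetLiver = TRUE, useLevelSetTumor = TRUE,
            useOtsuGate = TRUE, liverNet = NULL, tumorNet = NULL))

setValidity("PipelineConfig", function(object) {
  if (object@threshold <= 0 || object@threshold >= 1)
    return("threshold must be inside (0, 1)")
  if (object@medianKernel %% 2L == 0L) return("medianKernel must be odd")
  TRUE
})
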