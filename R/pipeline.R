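# Orchestration of the two-stage cascade: preprocess -> liver U-Net ->
# level-set liver refinement -> liver-ROI crop + edge-enhancing diffusion ->
# tumor U-Net -> level-set tumor refinement -> back to the original grid.
# Refinement runs on the network grid (cheaper, matches the network
# geometry) and masks are inverse-resized to the native grid afterwards.

largestComponent3D <- function(mask) {
  lab <- cpp_label3d(array(as.integer(mask != 0), dim = dim(mask)))
  if (max(lab) <= 1L) return((mask != 0) * 1L)
  counts <- tabulate(lab[lab > 0L])
  (lab == which.max(counts)) * 1L
}

withStageTag <- function(stage, expr) {
  tryCatch(expr, hepasegError = function(e) {
    e$message <- sprintf("[%s stage] %s", stage, conditionMessage(e))
    stop(e)
  })
}

liverGate <- function(img) {
  t <- tryCatch(otsuThreshold(img), hepasegDegenerateInput = function(e)
    NULL)
  if (is.null(t)) NULL else c(t, max(img) + 1)
}

# Otsu over the intensities inside the liver envelope separates tumor from
# parenchyma; the envelope restriction keeps the zeroed/blurred background
# ramp out of the histogram, which would otherwise dominate the threshold.
tumorGate <- function(img, envelope) {
  v <- img[envelope != 0]
  if (length(v) < 2 || length(unique(round(v, 8))) < 2) return(NULL)
  t <- tryCatch(otsuThreshold(matrix(v, ncol = 1)),
                hepasegDegenerateInput = function(e) NULL)
  if (is.null(t)) NULL else c(1e-6, t)
}

#' Segment the liver from a CT volume
#'
#' Window + median filter, per-slice network prediction at the network input
#' size, probability thresholding, largest 3D connected component,
#' inverse-resizing of the coarse mask to the original grid, then per-slice
#' localized level-set refinement at the native resolution with an
#' Otsu-derived intensity gate. Both the network-only and the refined mask
#' are returned for ablation.
#'
#' @param vol a [CTVolume-class] in HU.
#' @param cfg a [PipelineConfig-class] with a trained liver network.
#' @return list with `unet` and `refined` [BinaryMask-class] on the input
#'   grid.
#' @export
segmentLiver <- function(vol, cfg) {
  withStageTag("liver", {
    if (is.null(cfg@liverNet) || !cfg@liverNet@trained)
      stopWithClass("liver network is not trained", "hepasegContractError")
    med <- medianFilterVolume(huWindow(vol, cfg@window), cfg@medianKernel)
    sz <- cfg@liverNet@config@inputSize
    maps <- predictVolume(cfg@liverNet, med)
    bin <- binarizeMaps(maps, cfg@threshold)
    if (sum(bin) == 0L)
      stopWithClass("no liver found", "hepasegNoLiver")
    bin <- largestComponent3D(bin)
    srcDim <- dim(vol@voxels)
    rec <- new("ResampleRecord", sourceDim = srcDim[1:2],
               targetDim = c(sz, sz), order = "nearest")
    coarse <- array(0L, dim = srcDim)
    for (k in seq_len(srcDim[3]))
      coarse[, , k] <- (invertResizeSlice(bin[, , k] * 1.0, rec,
                                          "nearest") > 0.5) * 1L
    refined <- coarse
    if (cfg@useLevelSetLiver) {
      for (k in seq_len(srcDim[3])) {
        if (sum(coarse[, , k]) == 0L) next
        img <- med@voxels[, , k]
        gate <- if (cfg@useOtsuGate) liverGate(img) else NULL
        refined[, , k] <- evolveContour(img, coarse[, , k], cfg@liverLS,
                                        gate)
      }
      # the liver envelope is a single component by definition; refinement
      # can detach residual blobs, so the rule is applied again
      if (sum(refined) > 0L) refined <- largestComponent3D(refined)
    }
    list(unet = binaryMask(coarse, spacing = vol@spacing),
         refined = binaryMask(refined, spacing = vol@spacing))
  })
}

#' Segment tumors inside a segmented liver
#'
#' Crops the liver region of interest (background zeroed outside the liver
#' envelope), enhances it with edge-enhancing diffusion, predicts per-slice
#' tumor probability maps, maps the coarse mask back to the ROI grid, and
#' refines each slice with the localized level set at native resolution. The
#' gate keeps intensities at or below the Otsu threshold computed inside the
#' liver envelope of the slice (tumors are darker than enhanced parenchyma).
#' Results are pasted back onto the original grid and intersected with the
#' liver mask.
#'
#' @param vol a [CTVolume-class] in HU.
#' @param liver a nonempty liver [BinaryMask-class] on the same grid.
#' @param cfg a [PipelineConfig-class] with a trained tumor network.
#' @return list with `unet` and `refined` [BinaryMask-class] on the input
#'   grid, both subsets of `liver`.
#' @export
segmentTumors <- function(vol, liver, cfg) {
  withStageTag("tumor", {
    if (is.null(cfg@tumorNet) || !cfg@tumorNet@trained)
      stopWithClass("tumor network is not trained", "hepasegContractError")
    cr <- cropLiverROI(huWindow(vol, cfg@window), liver, cfg@roiMargin)
    roi <- eedFilter(cr$roi, cfg@eed)
    sz <- cfg@tumorNet@config@inputSize
    maps <- predictVolume(cfg@tumorNet, roi)
    bin <- binarizeMaps(maps, cfg@threshold)
    roiDim <- dim(roi@voxels)
    b <- cr$record@cropBox
    lroi <- liver@voxels[b[1, 1]:b[1, 2], b[2, 1]:b[2, 2],
                         b[3, 1]:b[3, 2], drop = FALSE]
    rec <- new("ResampleRecord", sourceDim = roiDim[1:2],
               targetDim = c(sz, sz), order = "nearest")
    coarse <- array(0L, dim = roiDim)
    for (k in seq_len(roiDim[3]))
      coarse[, , k] <- (invertResizeSlice(bin[, , k] * 1.0, rec,
                                          "nearest") > 0.5) * 1L
    refined <- coarse
    if (cfg@useLevelSetTumor) {
      for (k in seq_len(roiDim[3])) {
        if (sum(coarse[, , k]) == 0L) next
        img <- roi@voxels[, , k]
        gate <- if (cfg@useOtsuGate) tumorGate(img, lroi[, , k]) else NULL
        refined[, , k] <- evolveContour(img, coarse[, , k], cfg@tumorLS,
                                        gate)
      }
    }
    toFull <- function(crop) {
      full <- uncropToGrid(crop, cr$record)
      array(as.integer(full != 0 & liver@voxels != 0), dim = dim(full))
    }
    list(unet = binaryMask(toFull(coarse), spacing = vol@spacing),
         refined = binaryMask(toFull(refined), spacing = vol@spacing))
  })
}

#' Run the full two-stage cascade on one volume
#'
#' Deterministic given the trained networks and the configuration; the
#' provenance log records every parameter actually used.
#'
#' @param vol a [CTVolume-class] in HU.
#' @param cfg a [PipelineConfig-class] with both networks trained.
#' @return a [SegmentationResult-class].
#' @export
runPipeline <- function(vol, cfg) {
  validObject(cfg)
  lv <- segmentLiver(vol, cfg)
  tm <- segmentTumors(vol, lv$refined, cfg)
  prov <- list(
    window = c(lo = cfg@window@lo, hi = cfg@window@hi),
    medianKernel = cfg@medianKernel,
    eed = c(sigma = cfg@eed@sigma, rho = cfg@eed@rho,
            lambda = cfg@eed@lambda, tau = cfg@eed@tau,
            nSteps = cfg@eed@nSteps),
    threshold = cfg@threshold, roiMargin = cfg@roiMargin,
    liverLS = c(radius = cfg@liverLS@radius, mu = cfg@liverLS@mu,
                dt = cfg@liverLS@dt, maxIters = cfg@liverLS@maxIters),
    tumorLS = c(radius = cfg@tumorLS@radius, mu = cfg@tumorLS@mu,
                dt = cfg@tumorLS@dt, maxIters = cfg@tumorLS@maxIters),
    useLevelSetLiver = cfg@useLevelSetLiver,
    useLevelSetTumor = cfg@useLevelSetTumor,
    useOtsuGate = cfg@useOtsuGate,
    liverNetInput = cfg@liverNet@config@inputSize,
    tumorNetInput = cfg@tumorNet@config@inputSize)
  new("SegmentationResult", liver = lv$refined, tumor = tm$refined,
      liverUNet = lv$unet, tumorUNet = tm$unet, provenance = prov)
}
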