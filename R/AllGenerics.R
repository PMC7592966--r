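# Accessor generics and show methods.

#' Voxel array of a volume or mask
#' @param x a [CTVolume-class] or [BinaryMask-class].
#' @return the underlying 3D array.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname voxels
#' @export
setMethod("voxels", "CTVolume", function(x) x@voxels)

#' @rdname voxels
#' @export
setMethod("voxels", "BinaryMask", function(x) x@voxels)

#' Voxel spacing in mm
#' @param x a [CTVolume-class] or [BinaryMask-class].
#' @return numeric vector of length 3.
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname spacing
#' @export
setMethod("spacing", "CTVolume", function(x) x@spacing)

#' @rdname spacing
#' @export
setMethod("spacing", "BinaryMask", function(x) x@spacing)

#' @export
setMethod("dim", "CTVolume", function(x) dim(x@voxels))

#' @export
setMethod("dim", "BinaryMask", function(x) dim(x@voxels))

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("CTVolume %d x %d x %d, spacing %.2f x %.2f x %.2f mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat(sprintf("  intensity range [%.1f, %.1f]\n",
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("BinaryMask %d x %d x %d, %d foreground voxels\n",
              d[1], d[2], d[3], sum(object@voxels)))
})

setMethod("show", "UNetModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "UNetModel (%s): %dx%d input, depth %d, %d base filters, %d conv layers\n",
    if (nzchar(object@stage)) object@stage else "unassigned",
    cfg@inputSize, cfg@inputSize, cfg@depth, cfg@baseFilters,
    countConvLayers(cfg)))
  cat(sprintf("  %d parameters, %s\n",
              sum(vapply(object@params, length, integer(1))),
              if (object@trained) "trained" else "untrained"))
})

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf(
    "SegmentationResult: liver %d voxels (U-Net %d), tumor %d (U-Net %d)\n",
    sum(object@liver@voxels), sum(object@liverUNet@voxels),
    sum(object@tumor@voxels), sum(object@tumorUNet@voxels)))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec %dx%dx%d: liver %.0f+/-%.0f HU, tumors %.0f+/-%.0f HU, noise %.0f HU, seed %d\n",
    object@dim[1], object@dim[2], object@dim[3], object@liverHU,
    object@liverSD, object@tumorHU, object@tumorSD, object@noiseSD,
    object@seed))
})
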