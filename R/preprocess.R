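# Slice and volume preparation: HU windowing, median filtering for the liver
# stage, edge-enhancing diffusion for the tumor stage, and liver-ROI cropping
# for the cascade. Order of operations: window first, then median-filter.

#' Window Hounsfield intensities onto \[0, 1\]
#'
#' Computes (clip(x, lo, hi) - lo) / (hi - lo): monotone non-decreasing, maps
#' the window endpoints onto the range ends, and excludes irrelevant
#' structures (air, compact bone) from the usable contrast range.
#'
#' @param x a [CTVolume-class], [SliceImage-class], matrix or array in HU.
#' @param w a [WindowSpec-class]; default -50 to 250 HU.
#' @return same kind as `x` with values in \[0, 1\].
#' @export
huWindow <- function(x, w = windowSpec()) {
  validObject(w)
  f <- function(v) {
    v <- pmin(pmax(v, w@lo), w@hi)
    if (w@rescale) (v - w@lo) / (w@hi - w@lo) else v
  }
  if (is(x, "CTVolume"))
    return(ctVolume(f(x@voxels), spacing = x@spacing, header = x@header))
  if (is(x, "SliceImage")) {
    x@pixels <- f(x@pixels)
    return(x)
  }
  f(x)
}

#' Median filtering of a slice
#'
#' Each output pixel is the median of its odd square neighborhood (edges
#' reflected), improving intensity homogeneity inside the liver before the
#' liver network and level set see the slice.
#'
#' @param img a [SliceImage-class] or matrix.
#' @param kernel odd window size >= 3.
#' @return same kind as `img`.
#' @export
medianFilter2D <- function(img, kernel = 3L) {
  kernel <- as.integer(kernel)
  if (kernel < 3L || kernel %% 2L == 0L)
    stopWithClass("kernel must be odd and >= 3", "hepasegContractError")
  if (is(img, "SliceImage")) {
    img@pixels <- cpp_median_filter(img@pixels, kernel)
    return(img)
  }
  cpp_median_filter(as.matrix(img), kernel)
}

#' Median-filter every axial slice of a volume
#'
#' @param vol a [CTVolume-class].
#' @param kernel odd window size >= 3.
#' @return a [CTVolume-class].
#' @export
medianFilterVolume <- function(vol, kernel = 3L) {
  v <- vol@voxels
  for (k in seq_len(dim(v)[3]))
    v[, , k] <- medianFilter2D(v[, , k], kernel)
  ctVolume(v, spacing = vol@spacing, header = vol@header)
}

#' Tensor-based 3D edge-enhancing diffusion
#'
#' Explicit updates of u_t = div(D grad u) where the diffusion tensor D has
#' eigenvalue g(|grad u_sigma|^2) along the regularized gradient direction
#' and 1 on the orthogonal complement, with Weickert's diffusivity
#' g(s) = 1 - exp(-Cm/(s/lambda^2)^m) (g(0) = 1, decreasing). Smooths noise
#' inside homogeneous tissue while inhibiting flux across the liver/tumor
#' boundary, which raises the tumor-parenchyma contrast the tumor network and
#' level set rely on. The conservative face-flux discretization conserves the
#' intensity mean; the explicit step must satisfy
#' tau <= 1/(2 * (2 + 1/hz^2)) with hz the slice spacing in in-plane pixel
#' units (checked before iterating). Gradients are spacing-aware for
#' anisotropic voxels.
#'
#' @param vol a windowed [CTVolume-class] with intensities in \[0, 1\].
#' @param p an [EEDParams-class].
#' @return the diffused [CTVolume-class].
#' @export
eedFilter <- function(vol, p = eedParams()) {
  validObject(p)
  if (any(dim(vol@voxels) < 8L))
    stopWithClass("volume must span >= 8 voxels per axis",
                  "hepasegContractError")
  hz <- vol@spacing[3] / vol@spacing[1]
  tauMax <- 1 / (2 * (2 + 1 / hz^2))
  if (p@tau > tauMax)
    stopWithClass(sprintf("tau = %.3f exceeds the stability bound %.3f",
                          p@tau, tauMax), "hepasegContractError")
  out <- cpp_eed(vol@voxels, hz, p@sigma, p@rho, p@lambda, p@tau, p@nSteps,
                 p@m, p@Cm)
  ctVolume(out, spacing = vol@spacing, header = vol@header)
}

#' Crop a volume to the liver region of interest
#'
#' Takes the axis-aligned bounding box of the liver mask dilated by `margin`
#' (clipped to the grid) and zeroes all voxels outside the mask, producing
#' the liver envelope image the tumor network is trained on. Zero is the
#' window floor, so suppressed background and true window-floor tissue
#' coincide.
#'
#' @param vol a [CTVolume-class] (windowed).
#' @param liver a nonempty [BinaryMask-class] on the same grid.
#' @param margin box dilation in px (default 5, giving the level set room at
#'   the liver boundary).
#' @return list with `roi` ([CTVolume-class]) and `record`
#'   ([ResampleRecord-class] holding the crop box).
#' @export
cropLiverROI <- function(vol, liver, margin = 5L) {
  if (!identical(dim(vol@voxels), dim(liver@voxels)))
    stopWithClass("mask shape must equal volume shape",
                  "hepasegContractError")
  if (sum(liver@voxels) == 0L)
    stopWithClass("no liver found", "hepasegNoLiver")
  d <- dim(vol@voxels)
  idx <- which(liver@voxels != 0L, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - margin, 1L)
  hi <- pmin(apply(idx, 2, max) + margin, d)
  v <- vol@voxels * (liver@voxels != 0L)
  roi <- v[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  rec <- new("ResampleRecord", sourceDim = as.integer(d),
             targetDim = as.integer(dim(roi)), order = "nearest",
             cropBox = cbind(as.integer(lo), as.integer(hi)))
  list(roi = ctVolume(roi, spacing = vol@spacing, header = vol@header),
       record = rec)
}

#' Paste a cropped-grid array back onto the original grid
#'
#' Inverse of the crop in [cropLiverROI()]; voxels outside the crop box are
#' zero.
#'
#' @param arr array at the record's crop size.
#' @param record the [ResampleRecord-class] from [cropLiverROI()].
#' @return array at the record's source size.
#' @export
uncropToGrid <- function(arr, record) {
  if (nrow(record@cropBox) != 3L)
    stopWithClass("record has no crop box", "hepasegContractError")
  out <- array(0, dim = record@sourceDim)
  b <- record@cropBox
  out[b[1, 1]:b[1, 2], b[2, 1]:b[2, 2], b[3, 1]:b[3, 2]] <- arr
  out
}
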