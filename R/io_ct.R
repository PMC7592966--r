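# NIfTI input/output, slice extraction and resizing.
#
# Conventions: the axial plane is the third array axis (the LiTS layout);
# indices are (row, column) = (y, x) within a slice. Masks are written as
# unsigned 8-bit. Label volumes follow the LiTS encoding: label 1 = liver,
# label 2 = tumor inside the liver, so {1,2} -> liver and {2} -> tumor.

#' Read a CT volume from a NIfTI file
#'
#' @param path path to a .nii or .nii.gz file containing a 3D image.
#' @return a [CTVolume-class] with spacing taken from the header and
#'   intensities unmodified.
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stopWithClass(sprintf("expected a 3D image, got %d dimensions",
                          length(d)), "hepasegFormatError")
  sp <- attr(img, "pixdim")
  if (is.null(sp) || length(sp) < 3L) sp <- c(1, 1, 1)
  ctVolume(array(as.numeric(img), dim = d), spacing = abs(sp[1:3]),
           header = RNifti::niftiHeader(img))
}

#' Write a CT volume to a NIfTI file
#'
#' @param vol a [CTVolume-class].
#' @param path output path (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
writeVolume <- function(vol, path) {
  arr <- vol@voxels
  attr(arr, "pixdim") <- vol@spacing
  img <- if (is.null(vol@header)) RNifti::asNifti(arr)
         else RNifti::asNifti(arr, reference = vol@header)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a binary mask aligned with a reference volume
#'
#' @param mask a [BinaryMask-class] with values in \{0,1\}.
#' @param ref the [CTVolume-class] the mask lives on.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeMask <- function(mask, ref, path) {
  if (!identical(dim(mask@voxels), dim(ref@voxels)))
    stopWithClass("mask shape must equal reference volume shape",
                  "hepasegContractError")
  if (!all(mask@voxels %in% c(0L, 1L)))
    stopWithClass("mask values must be exactly 0 or 1",
                  "hepasegContractError")
  arr <- array(as.integer(mask@voxels), dim(mask@voxels))
  attr(arr, "pixdim") <- ref@spacing
  img <- if (is.null(ref@header))
    RNifti::asNifti(arr, datatype = "uint8")
  else RNifti::asNifti(arr, reference = ref@header, datatype = "uint8")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a label volume and split it into liver and tumor masks
#'
#' LiTS-style labels: 1 = liver parenchyma, 2 = tumor (inside the liver).
#' Any other nonzero label is coerced to liver with a warning.
#'
#' @param path path to a NIfTI label volume.
#' @return list with `liver` and `tumor` [BinaryMask-class] objects
#'   (tumor voxels are liver voxels too).
#' @export
readLabelVolume <- function(path) {
  vol <- readVolume(path)
  lab <- round(vol@voxels)
  other <- lab[lab != 0 & lab != 1 & lab != 2]
  if (length(other) > 0) {
    warning(sprintf("coercing %d voxels with labels outside {1,2} to liver",
                    length(other)))
    lab[lab != 0 & lab != 2] <- 1
  }
  list(liver = binaryMask(lab >= 1, spacing = vol@spacing),
       tumor = binaryMask(lab == 2, spacing = vol@spacing))
}

#' Extract the ordered axial slices of a volume
#'
#' @param vol a [CTVolume-class] (or [BinaryMask-class]).
#' @param volumeId identifier recorded in each slice's provenance.
#' @return list of [SliceImage-class], one per index along the axial axis in
#'   ascending order; slice k pixel (i,j) equals voxel (i,j,k).
#' @export
extractSlices <- function(vol, volumeId = NA_character_) {
  v <- voxels(vol)
  lapply(seq_len(dim(v)[3]), function(k)
    new("SliceImage", pixels = v[, , k, drop = TRUE] * 1.0,
        volumeId = volumeId, index = as.integer(k)))
}

#' Stack slices (or matrices) back into a 3D array
#'
#' The inverse of [extractSlices()].
#'
#' @param slices list of [SliceImage-class] or matrices, in slice order.
#' @return 3D array.
#' @export
stackSlices <- function(slices) {
  mats <- lapply(slices, asPixelMatrix)
  d <- dim(mats[[1]])
  array(unlist(mats, use.names = FALSE), dim = c(d, length(mats)))
}

#' Resize a slice, keeping a record sufficient to invert the transform
#'
#' Bilinear interpolation for intensities, nearest-neighbor for masks.
#'
#' @param s a [SliceImage-class] or matrix.
#' @param target target (rows, cols), both >= 8.
#' @param order "bilinear" or "nearest".
#' @return list with `slice` (matrix at the target size) and `record`
#'   (a [ResampleRecord-class]).
#' @export
resizeSlice <- function(s, target = c(256L, 256L),
                        order = c("bilinear", "nearest")) {
  order <- match.arg(order)
  m <- asPixelMatrix(s)
  target <- as.integer(target)
  if (any(target < 8L))
    stopWithClass("target dimensions must be >= 8", "hepasegContractError")
  out <- resizeMatrix(m, target, order)
  rec <- new("ResampleRecord", sourceDim = dim(m), targetDim = target,
             order = order)
  list(slice = out, record = rec)
}

#' Invert a recorded slice resize
#'
#' @param m matrix at the record's target size.
#' @param record the [ResampleRecord-class] from [resizeSlice()].
#' @param order interpolation for the inverse ("nearest" for masks).
#' @return matrix at the record's source size.
#' @export
invertResizeSlice <- function(m, record, order = record@order) {
  resizeMatrix(m, record@sourceDim, order)
}
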