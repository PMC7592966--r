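# Dice-per-case evaluation and ablation reporting.

#' Dice overlap of two binary masks
#'
#' 2|A intersect B| / (|A| + |B|): the ratio of correctly segmented voxels to
#' the average size of segmentation and ground truth. Two empty masks are
#' defined to agree perfectly (Dice 1), configurable via `emptyValue`.
#'
#' @param a,b [BinaryMask-class] objects or arrays/matrices of \{0,1\} with
#'   equal shape.
#' @param emptyValue value returned when both masks are empty.
#' @return scalar in \[0, 1\].
#' @export
diceCoefficient <- function(a, b, emptyValue = 1.0) {
  av <- if (is(a, "BinaryMask")) a@voxels else a
  bv <- if (is(b, "BinaryMask")) b@voxels else b
  if (!identical(dim(av), dim(bv)))
    stopWithClass("mask shapes must match", "hepasegContractError")
  sa <- sum(av != 0)
  sb <- sum(bv != 0)
  if (sa + sb == 0) return(emptyValue)
  2 * sum(av != 0 & bv != 0) / (sa + sb)
}

#' Evaluate segmentation results against ground truth, per case
#'
#' Computes volume-level (per-case) Dice for the liver and tumor stages,
#' both for the network-only and the level-set-refined masks, and arithmetic
#' means over cases. Cases whose ground truth has no tumor are flagged and
#' excluded from the tumor means (their tumor Dice would be 1 for an empty
#' prediction by the empty-vs-empty convention and is reported separately).
#'
#' @param preds named list per case: each element a [SegmentationResult-class]
#'   or a list with `liver`, `tumor`, `liverUNet`, `tumorUNet` masks.
#' @param truths named list per case with `liver` and `tumor` masks.
#' @return list with `scores` (one row per case) and `means` (named numeric;
#'   tumor means over tumor-bearing cases only).
#' @export
evaluateCases <- function(preds, truths) {
  ids <- names(preds)
  if (is.null(ids) || !setequal(ids, names(truths))) {
    miss <- c(setdiff(names(preds), names(truths)),
              setdiff(names(truths), names(preds)))
    stopWithClass(paste("unmatched case ids:",
                        paste(unique(miss), collapse = ", ")),
                  "hepasegContractError")
  }
  getm <- function(p, nm) {
    if (is(p, "SegmentationResult")) slot(p, nm)
    else p[[nm]]
  }
  rows <- lapply(ids, function(id) {
    p <- preds[[id]]
    tr <- truths[[id]]
    tumorFree <- sum(if (is(tr$tumor, "BinaryMask")) tr$tumor@voxels else
      tr$tumor) == 0
    data.frame(
      case_id = id,
      liver_dice_unet = diceCoefficient(getm(p, "liverUNet"), tr$liver),
      liver_dice_refined = diceCoefficient(getm(p, "liver"), tr$liver),
      tumor_dice_unet = diceCoefficient(getm(p, "tumorUNet"), tr$tumor),
      tumor_dice_refined = diceCoefficient(getm(p, "tumor"), tr$tumor),
      tumor_free = tumorFree)
  })
  scores <- do.call(rbind, rows)
  tb <- !scores$tumor_free
  means <- c(liver_dice_unet = mean(scores$liver_dice_unet),
             liver_dice_refined = mean(scores$liver_dice_refined),
             tumor_dice_unet = if (any(tb))
               mean(scores$tumor_dice_unet[tb]) else NA_real_,
             tumor_dice_refined = if (any(tb))
               mean(scores$tumor_dice_refined[tb]) else NA_real_)
  list(scores = scores, means = means)
}
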