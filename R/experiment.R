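# The self-contained phantom study: train both cascade stages on synthetic
# phantoms and evaluate Dice per case on held-out phantoms. This is the
# package's scaled-down counterpart of a full CT study: 128x128x48 phantom
# grids, 64x64-input 8-base-filter networks (depth 4 for the liver stage —
# the default 19-convolution architecture at reduced scale, whose full-slice
# bottleneck lets it tell liver-free slices apart — and depth 3 for the
# tumor stage, where small lesions vanish in a deeper bottleneck), trained
# with the standard recipe (soft-Dice loss, Adam 0.001, 20 epochs, batch
# 32, learning rate x0.1 on a 5-epoch plateau).

#' Train both cascade stages on phantoms
#'
#' @param cases list of phantom triples from [generateCorpus()].
#' @param netSize,baseFilters network scale for the study.
#' @param liverDepth,tumorDepth pooling depth per stage: the liver network
#'   needs the whole-slice receptive field of depth 4 to tell liver-free
#'   slices apart, while the tumor network does better at depth 3 — small
#'   lesions vanish in a deeper bottleneck.
#' @param tc a [TrainingConfig-class] (defaults to the standard recipe).
#' @param lsRadius localization radius for the native-grid refinement.
#' @param sliceStride training-slice subsampling stride per volume.
#' @param seed seed for weight initialization (training seeds come from
#'   `tc@seed`).
#' @param verbose print per-epoch training lines.
#' @return a [PipelineConfig-class] with both networks trained, plus
#'   training histories in `attr(, "histories")`.
#' @export
trainCascade <- function(cases, netSize = 64L, liverDepth = 4L,
                         tumorDepth = 3L, baseFilters = 8L,
                         tc = trainingConfig(), lsRadius = 7, seed = 1L,
                         sliceStride = 2L, verbose = FALSE) {
  vols <- lapply(cases, `[[`, "volume")
  livers <- lapply(cases, `[[`, "liver")
  tumors <- lapply(cases, `[[`, "tumor")
  liverCfg <- unetConfig(inputSize = netSize, depth = liverDepth,
                         baseFilters = baseFilters)
  tumorCfg <- unetConfig(inputSize = netSize, depth = tumorDepth,
                         baseFilters = baseFilters)
  dsL <- selectTrainingSlices(vols, livers, stage = "liver",
                              inputSize = netSize,
                              sliceStride = sliceStride)
  trL <- trainUNet(buildUNet(liverCfg, seed = seed, stage = "liver"), dsL,
                   tc, verbose = verbose)
  dsT <- selectTrainingSlices(vols, livers, tumors, stage = "tumor",
                              inputSize = netSize,
                              sliceStride = sliceStride)
  tcT <- tc
  tcT@seed <- tc@seed + 1L
  trT <- trainUNet(buildUNet(tumorCfg, seed = seed + 1L, stage = "tumor"),
                   dsT, tcT, verbose = verbose)
  cfg <- pipelineConfig(
    liverNet = trL$model, tumorNet = trT$model,
    liverLS = levelSetParams(radius = lsRadius, maxIters = 200L),
    tumorLS = levelSetParams(radius = lsRadius, maxIters = 100L))
  attr(cfg, "histories") <- list(liver = trL$history, tumor = trT$history)
  cfg
}

#' Run the end-to-end phantom study
#'
#' Generates a phantom corpus, trains both stages on the first `nTrain`
#' cases, segments the remaining `nTest` held-out cases with the full
#' cascade, and evaluates Dice per case for the network-only and the
#' level-set-refined masks.
#'
#' @param nTrain,nTest corpus split (defaults 40 / 10).
#' @param seed seed governing phantom generation and training.
#' @param spec base [PhantomSpec-class] of the corpus.
#' @param netSize,liverDepth,tumorDepth,baseFilters network scale (see
#'   [trainCascade()]).
#' @param tc a [TrainingConfig-class].
#' @param verbose print progress.
#' @return list with `evaluation` (scores and means from [evaluateCases()]),
#'   `config` (the trained [PipelineConfig-class]), `results` (per-case
#'   [SegmentationResult-class]), `manifest`, and `histories`.
#' @export
runPhantomStudy <- function(nTrain = 40L, nTest = 10L, seed = 7L,
                            spec = phantomSpec(), netSize = 64L,
                            liverDepth = 4L, tumorDepth = 3L,
                            baseFilters = 8L, tc = trainingConfig(),
                            verbose = FALSE) {
  corpus <- generateCorpus(nTrain + nTest, spec, seed = seed)
  trainCases <- corpus$cases[seq_len(nTrain)]
  testCases <- corpus$cases[nTrain + seq_len(nTest)]
  tc@seed <- as.integer(seed)
  cfg <- trainCascade(trainCases, netSize = netSize,
                      liverDepth = liverDepth, tumorDepth = tumorDepth,
                      baseFilters = baseFilters, tc = tc, seed = seed,
                      verbose = verbose)
  results <- lapply(testCases, function(cs) runPipeline(cs$volume, cfg))
  truths <- lapply(testCases, function(cs)
    list(liver = cs$liver, tumor = cs$tumor))
  ev <- evaluateCases(results, truths)
  if (verbose) {
    m <- ev$means
    message(sprintf(
      "liver dice: unet %.3f refined %.3f | tumor dice: unet %.3f refined %.3f",
      m["liver_dice_unet"], m["liver_dice_refined"], m["tumor_dice_unet"],
      m["tumor_dice_refined"]))
  }
  list(evaluation = ev, config = cfg, results = results,
       manifest = corpus$manifest, histories = attr(cfg, "histories"))
}
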