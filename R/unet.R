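# Compact CPU implementation of the 2D U-Net used by both cascade stages:
# a contracting path of 3x3 convolution blocks (channels doubled, resolution
# halved per level), an expanding path of 2x2 transposed convolutions with
# skip concatenations followed by one 3x3 convolution per level, dropout
# before the output layer, and a 1x1 sigmoid output giving a per-pixel
# probability. With the default configuration (depth 4, two convolutions per
# contracting block) the layer audit gives exactly 19 convolutional layers.
# Convolution/pooling kernels live in src/conv_ops.cpp; the graph, the
# soft-Dice loss and the Adam optimizer are here.

levelFilters <- function(cfg, i) cfg@baseFilters * 2L^(i - 1L)

#' Count the convolutional layers of a configuration
#'
#' Counts 3x3 convolutions, 2x2 transposed convolutions and the 1x1 output
#' convolution.
#'
#' @param cfg a [UNetConfig-class] or [UNetModel-class].
#' @return integer layer count (19 at the defaults).
#' @export
countConvLayers <- function(cfg) {
  if (is(cfg, "UNetModel")) cfg <- cfg@config
  as.integer((cfg@depth + 1L) * cfg@convPerBlock + 2L * cfg@depth + 1L)
}

heInit <- function(dims, fanIn) {
  array(rnorm(prod(dims), sd = sqrt(2 / fanIn)), dim = dims)
}

#' Build an untrained U-Net
#'
#' @param cfg a [UNetConfig-class].
#' @param seed RNG seed for He weight initialization.
#' @param stage optional stage tag ("liver" or "tumor").
#' @return a [UNetModel-class] mapping (inputSize, inputSize, 1) slices to
#'   probability maps in \[0, 1\] of the same size.
#' @export
buildUNet <- function(cfg = unetConfig(), seed = 1L, stage = "") {
  validObject(cfg)
  set.seed(seed)
  d <- cfg@depth
  cpb <- cfg@convPerBlock
  P <- list()
  cin <- 1L
  for (i in seq_len(d)) {
    f <- levelFilters(cfg, i)
    for (cc in seq_len(cpb)) {
      nm <- sprintf("enc%d.conv%d", i, cc)
      P[[paste0(nm, ".W")]] <- heInit(c(3, 3, cin, f), 9 * cin)
      P[[paste0(nm, ".b")]] <- numeric(f)
      cin <- f
    }
  }
  fbot <- levelFilters(cfg, d + 1L)
  for (cc in seq_len(cpb)) {
    nm <- sprintf("bot.conv%d", cc)
    P[[paste0(nm, ".W")]] <- heInit(c(3, 3, cin, fbot), 9 * cin)
    P[[paste0(nm, ".b")]] <- numeric(fbot)
    cin <- fbot
  }
  for (i in rev(seq_len(d))) {
    f <- levelFilters(cfg, i)
    P[[sprintf("dec%d.up.W", i)]] <- heInit(c(2, 2, cin, f), 4 * cin)
    P[[sprintf("dec%d.up.b", i)]] <- numeric(f)
    P[[sprintf("dec%d.conv.W", i)]] <- heInit(c(3, 3, 2L * f, f), 9 * 2 * f)
    P[[sprintf("dec%d.conv.b", i)]] <- numeric(f)
    cin <- f
  }
  P[["out.W"]] <- heInit(c(cin, 1), cin)
  # background-prior initialization: starting near p = 0.12 instead of 0.5
  # skips the chaotic all-foreground phase, which otherwise decides whether
  # a short training run lands in a false-positive-heavy basin
  P[["out.b"]] <- -2
  new("UNetModel", config = cfg, params = P, stage = stage, trained = FALSE)
}

asInputBatch <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1, 1))
  if (length(dim(x)) == 3L) x <- array(x, dim = c(dim(x)[1:2], 1, dim(x)[3]))
  x
}

conv1x1Forward <- function(h, W, b) {
  dm <- dim(h)
  H <- dm[1]; Wd <- dm[2]; C <- dm[3]; N <- dm[4]
  M <- matrix(h, nrow = H * Wd)
  out <- array(0, dim = c(H, Wd, 1, N))
  for (n in seq_len(N))
    out[, , 1, n] <- matrix(M[, ((n - 1) * C + 1):(n * C)] %*% W + b, H, Wd)
  out
}

conv1x1Backward <- function(h, W, dz) {
  dm <- dim(h)
  H <- dm[1]; Wd <- dm[2]; C <- dm[3]; N <- dm[4]
  M <- matrix(h, nrow = H * Wd)
  G <- matrix(dz, nrow = H * Wd)
  dW <- matrix(0, C, 1)
  dh <- array(0, dim = dm)
  for (n in seq_len(N)) {
    cols <- ((n - 1) * C + 1):(n * C)
    dW <- dW + crossprod(M[, cols, drop = FALSE], G[, n])
    dh[, , , n] <- array(tcrossprod(G[, n], W[, 1]), dim = c(H, Wd, C))
  }
  list(dh = dh, dW = dW, db = sum(G))
}

# Forward pass; returns the probability maps and (optionally) the cache
# needed by the backward pass.
unetForward <- function(model, x, training = FALSE, keepCache = training) {
  cfg <- model@config
  P <- model@params
  d <- cfg@depth
  cpb <- cfg@convPerBlock
  x <- asInputBatch(x)
  cache <- list(convX = list(), convZ = list(), poolIdx = list(),
                poolDim = list(), upX = list(), catC = integer(d))
  h <- x
  blocks <- c(lapply(seq_len(d), function(i) sprintf("enc%d", i)), "bot")
  for (bi in seq_along(blocks)) {
    for (cc in seq_len(cpb)) {
      nm <- sprintf("%s.conv%d", blocks[[bi]], cc)
      z <- cpp_conv3_forward(h, P[[paste0(nm, ".W")]], P[[paste0(nm, ".b")]])
      if (keepCache) {
        cache$convX[[nm]] <- h
        cache$convZ[[nm]] <- z
      }
      h <- z * (z > 0)
    }
    if (bi <= d) {
      cache$skips[[bi]] <- h
      pl <- cpp_maxpool2_forward(h)
      if (keepCache) {
        cache$poolIdx[[bi]] <- pl$idx
        cache$poolDim[[bi]] <- dim(h)[1:2]
      }
      h <- pl$y
    }
  }
  for (i in rev(seq_len(d))) {
    nmu <- sprintf("dec%d.up", i)
    if (keepCache) cache$upX[[nmu]] <- h
    up <- cpp_upconv2_forward(h, P[[paste0(nmu, ".W")]],
                              P[[paste0(nmu, ".b")]])
    sk <- cache$skips[[i]]
    du <- dim(up)
    cache$catC[i] <- du[3]
    hcat <- array(0, dim = c(du[1], du[2], du[3] + dim(sk)[3], du[4]))
    hcat[, , seq_len(du[3]), ] <- up
    hcat[, , du[3] + seq_len(dim(sk)[3]), ] <- sk
    nmc <- sprintf("dec%d.conv", i)
    z <- cpp_conv3_forward(hcat, P[[paste0(nmc, ".W")]],
                           P[[paste0(nmc, ".b")]])
    if (keepCache) {
      cache$convX[[nmc]] <- hcat
      cache$convZ[[nmc]] <- z
    }
    h <- z * (z > 0)
  }
  if (training && cfg@dropoutRate > 0) {
    mask <- array((runif(length(h)) >= cfg@dropoutRate) /
                    (1 - cfg@dropoutRate), dim = dim(h))
    h <- h * mask
    if (keepCache) cache$dropMask <- mask
  }
  if (keepCache) cache$preOut <- h
  z <- conv1x1Forward(h, P[["out.W"]], P[["out.b"]])
  p <- 1 / (1 + exp(-z))
  if (keepCache) cache$prob <- p
  list(prob = p, cache = if (keepCache) cache else NULL)
}

# Backward pass: gradient of the scalar loss wrt every parameter, given
# dL/dprob. Returns a named list matching model@params.
unetBackward <- function(model, cache, dprob) {
  cfg <- model@config
  P <- model@params
  d <- cfg@depth
  cpb <- cfg@convPerBlock
  G <- list()
  p <- cache$prob
  dz <- dprob * p * (1 - p)
  ob <- conv1x1Backward(cache$preOut, P[["out.W"]], dz)
  G[["out.W"]] <- ob$dW
  G[["out.b"]] <- ob$db
  dh <- ob$dh
  if (!is.null(cache$dropMask)) dh <- dh * cache$dropMask
  convBack <- function(nm, dh) {
    z <- cache$convZ[[nm]]
    dzc <- dh * (z > 0)
    bk <- cpp_conv3_backward(cache$convX[[nm]], P[[paste0(nm, ".W")]], dzc)
    G[[paste0(nm, ".W")]] <<- bk$dW
    G[[paste0(nm, ".b")]] <<- bk$db
    bk$dx
  }
  dskips <- vector("list", d)
  for (i in seq_len(d)) {
    dcat <- convBack(sprintf("dec%d.conv", i), dh)
    cu <- cache$catC[i]
    dup <- dcat[, , seq_len(cu), , drop = FALSE]
    dskips[[i]] <- dcat[, , (cu + 1):dim(dcat)[3], , drop = FALSE]
    nmu <- sprintf("dec%d.up", i)
    bk <- cpp_upconv2_backward(cache$upX[[nmu]], P[[paste0(nmu, ".W")]], dup)
    G[[paste0(nmu, ".W")]] <- bk$dW
    G[[paste0(nmu, ".b")]] <- bk$db
    dh <- bk$dx
  }
  for (cc in rev(seq_len(cpb))) dh <- convBack(sprintf("bot.conv%d", cc), dh)
  for (i in rev(seq_len(d))) {
    pd <- cache$poolDim[[i]]
    dh <- cpp_maxpool2_backward(dh, cache$poolIdx[[i]], pd[1], pd[2])
    dh <- dh + dskips[[i]]
    for (cc in rev(seq_len(cpb)))
      dh <- convBack(sprintf("enc%d.conv%d", i, cc), dh)
  }
  G
}

#' Soft-Dice loss of predicted probability maps
#'
#' loss = 1 - (2 sum(p t) + eps) / (sum(p) + sum(t) + eps), computed per
#' sample and averaged over the batch. Differentiable in the predictions; on
#' binary predictions it equals 1 - Dice as eps tends to 0.
#'
#' @param pred probabilities in \[0, 1\]: matrix, or array with samples in
#'   the last dimension.
#' @param target binary targets of the same shape.
#' @param eps smoothing constant (default 1).
#' @return scalar loss in \[0, 1\].
#' @export
softDiceLoss <- function(pred, target, eps = 1) {
  softDiceLossGrad(pred, target, eps, wantGrad = FALSE)$loss
}

softDiceLossGrad <- function(pred, target, eps = 1, wantGrad = TRUE) {
  if (!identical(dim(pred), dim(target)) &&
      !identical(length(pred), length(target)))
    stopWithClass("pred and target shapes must match",
                  "hepasegContractError")
  pred <- asInputBatch(pred)
  target <- asInputBatch(target)
  N <- dim(pred)[4]
  ps <- matrix(pred, ncol = N)
  ts <- matrix(target, ncol = N)
  num <- 2 * colSums(ps * ts) + eps
  den <- colSums(ps) + colSums(ts) + eps
  loss <- mean(1 - num / den)
  grad <- NULL
  if (wantGrad) {
    g <- -(2 * ts * rep(den, each = nrow(ts)) -
             rep(num, each = nrow(ts))) / rep(den^2, each = nrow(ts)) / N
    grad <- array(g, dim = dim(pred))
  }
  list(loss = loss, grad = grad)
}

#' Assemble the training dataset of one cascade stage
#'
#' Liver stage: axial slices whose liver mask is nonempty, paired with the
#' whole-abdomen windowed and median-filtered slice resized to the network
#' input. Tumor stage: liver-ROI slices (cropped with the liver mask,
#' enhanced by edge-enhancing diffusion) whose tumor mask is nonempty;
#' volumes without any tumor annotation are excluded entirely. Slices whose
#' target is empty are excluded from training in both stages.
#'
#' @param volumes list of [CTVolume-class] in HU.
#' @param liverMasks list of liver [BinaryMask-class], aligned with
#'   `volumes`.
#' @param tumorMasks list of tumor [BinaryMask-class] (tumor stage only).
#' @param stage "liver" or "tumor".
#' @param inputSize network input side length.
#' @param window HU window.
#' @param medianKernel liver-stage median kernel.
#' @param eed tumor-stage diffusion parameters.
#' @param roiMargin liver-box dilation in px.
#' @param sliceStride keep every `sliceStride`-th qualifying slice per
#'   volume (adjacent CT slices are highly redundant; the phantom study uses
#'   stride 2).
#' @return a [SliceDataset-class].
#' @export
selectTrainingSlices <- function(volumes, liverMasks, tumorMasks = NULL,
                                 stage = c("liver", "tumor"),
                                 inputSize = 256L, window = windowSpec(),
                                 medianKernel = 3L, eed = eedParams(),
                                 roiMargin = 5L, sliceStride = 1L) {
  stage <- match.arg(stage)
  xs <- list()
  ys <- list()
  prov <- list()
  inputSize <- as.integer(inputSize)
  for (vi in seq_along(volumes)) {
    vol <- volumes[[vi]]
    liver <- liverMasks[[vi]]
    if (stage == "liver") {
      wv <- huWindow(vol, window)
      keep <- which(apply(liver@voxels, 3, sum) > 0)
      if (length(keep) > 0)
        keep <- keep[seq(1, length(keep), by = sliceStride)]
      for (k in keep) {
        tgt <- resizeSlice(liver@voxels[, , k] * 1.0,
                           c(inputSize, inputSize), "nearest")$slice
        if (sum(tgt) == 0) next  # tiny section lost in the resize
        inp <- medianFilter2D(wv@voxels[, , k], medianKernel)
        xs[[length(xs) + 1L]] <-
          resizeSlice(inp, c(inputSize, inputSize), "bilinear")$slice
        ys[[length(ys) + 1L]] <- tgt
        prov[[length(prov) + 1L]] <- c(vi, k)
      }
    } else {
      tumor <- tumorMasks[[vi]]
      if (sum(tumor@voxels) == 0L) next  # unannotated volume: excluded
      cr <- cropLiverROI(huWindow(vol, window), liver, roiMargin)
      roi <- eedFilter(cr$roi, eed)
      b <- cr$record@cropBox
      troi <- tumor@voxels[b[1, 1]:b[1, 2], b[2, 1]:b[2, 2],
                           b[3, 1]:b[3, 2], drop = FALSE]
      keep <- which(apply(troi, 3, sum) > 0)
      if (length(keep) > 0)
        keep <- keep[seq(1, length(keep), by = sliceStride)]
      for (k in keep) {
        tgt <- resizeSlice(troi[, , k] * 1.0, c(inputSize, inputSize),
                           "nearest")$slice
        if (sum(tgt) == 0) next  # tiny section lost in the resize
        xs[[length(xs) + 1L]] <-
          resizeSlice(roi@voxels[, , k], c(inputSize, inputSize),
                      "bilinear")$slice
        ys[[length(ys) + 1L]] <- tgt
        prov[[length(prov) + 1L]] <- c(vi, k)
      }
    }
  }
  if (length(xs) == 0L)
    stopWithClass("no qualifying training slices", "hepasegEmptyDataset")
  n <- length(xs)
  pv <- do.call(rbind, prov)
  new("SliceDataset",
      x = array(unlist(xs), dim = c(inputSize, inputSize, 1, n)),
      y = array(as.numeric(unlist(ys) > 0.5),
                dim = c(inputSize, inputSize, 1, n)),
      stage = stage,
      provenance = data.frame(case = pv[, 1], slice = pv[, 2]))
}

adamStep <- function(P, G, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(G)) {
    g <- G[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    P[[nm]] <- P[[nm]] - lr * (state$m[[nm]] / b1t) /
      (sqrt(state$v[[nm]] / b2t) + eps)
  }
  list(P = P, state = state)
}

#' Train a U-Net with the soft-Dice loss
#'
#' Adam optimization; the learning rate is multiplied by `lrFactor` whenever
#' the monitored loss (validation loss when a validation split exists,
#' otherwise training loss) fails to improve for `lrPatience` consecutive
#' epochs. Reproducible given `tc@seed`.
#'
#' @param model an untrained or trained [UNetModel-class].
#' @param ds a [SliceDataset-class].
#' @param tc a [TrainingConfig-class].
#' @param verbose print one line per epoch.
#' @return list with `model` (trained) and `history` (data.frame epoch,
#'   loss, val_loss, val_dice, lr).
#' @export
trainUNet <- function(model, ds, tc = trainingConfig(), verbose = FALSE) {
  n <- dim(ds@x)[4]
  if (n == 0L) stopWithClass("empty dataset", "hepasegEmptyDataset")
  hist0 <- data.frame(epoch = integer(), loss = numeric(),
                      val_loss = numeric(), val_dice = numeric(),
                      lr = numeric())
  if (tc@epochs == 0L) return(list(model = model, history = hist0))
  set.seed(tc@seed)
  nVal <- floor(tc@validationFraction * n)
  perm <- sample(n)
  valIdx <- if (nVal > 0) perm[seq_len(nVal)] else integer()
  trIdx <- setdiff(perm, valIdx)
  P <- model@params
  state <- list(t = 0, m = lapply(P, function(p) p * 0),
                v = lapply(P, function(p) p * 0))
  lr <- tc@lr0
  best <- Inf
  wait <- 0L
  rows <- vector("list", tc@epochs)
  for (ep in seq_len(tc@epochs)) {
    ord <- sample(trIdx)
    bl <- split(ord, ceiling(seq_along(ord) / tc@batchSize))
    eploss <- 0
    for (bb in bl) {
      xb <- ds@x[, , , bb, drop = FALSE]
      yb <- ds@y[, , , bb, drop = FALSE]
      model@params <- P
      fw <- unetForward(model, xb, training = TRUE)
      lg <- softDiceLossGrad(fw$prob, yb)
      G <- unetBackward(model, fw$cache, lg$grad)
      upd <- adamStep(P, G, state, lr)
      P <- upd$P
      state <- upd$state
      eploss <- eploss + lg$loss * length(bb)
    }
    eploss <- eploss / length(ord)
    valLoss <- NA_real_
    valDice <- NA_real_
    if (nVal > 0) {
      model@params <- P
      pv <- unetForward(model, ds@x[, , , valIdx, drop = FALSE],
                        training = FALSE)$prob
      yv <- ds@y[, , , valIdx, drop = FALSE]
      valLoss <- softDiceLoss(pv, yv)
      pb <- (pv >= 0.5) * 1
      valDice <- mean(vapply(seq_len(nVal), function(s) {
        a <- pb[, , 1, s]
        b <- yv[, , 1, s]
        if (sum(a) + sum(b) == 0) 1 else 2 * sum(a * b) / (sum(a) + sum(b))
      }, numeric(1)))
    }
    monitored <- if (nVal > 0) valLoss else eploss
    if (monitored < best - 1e-6) {
      best <- monitored
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= tc@lrPatience) {
        lr <- lr * tc@lrFactor
        wait <- 0L
      }
    }
    rows[[ep]] <- data.frame(epoch = ep, loss = eploss, val_loss = valLoss,
                             val_dice = valDice, lr = lr)
    if (verbose)
      message(sprintf("epoch %d: loss %.4f val %.4f dice %.4f lr %g", ep,
                      eploss, valLoss, valDice, lr))
  }
  model@params <- P
  model@trained <- TRUE
  model@stage <- if (nzchar(model@stage)) model@stage else ds@stage
  list(model = model, history = do.call(rbind, rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict probability maps for every axial slice of a volume
#'
#' Slices are resized to the network input with bilinear interpolation and
#' pushed through the network in mini-batches; one map per slice is returned
#' in ascending slice order, values in \[0, 1\]. Inference is deterministic
#' (dropout disabled).
#'
#' @param model a trained [UNetModel-class].
#' @param vol a preprocessed [CTVolume-class].
#' @param batchSize inference batch size.
#' @return list of probability-map matrices at the network input size.
#' @export
predictVolume <- function(model, vol, batchSize = 32L) {
  sz <- model@config@inputSize
  v <- voxels(vol)
  nk <- dim(v)[3]
  x <- array(0, dim = c(sz, sz, 1, nk))
  for (k in seq_len(nk))
    x[, , 1, k] <- resizeSlice(v[, , k], c(sz, sz), "bilinear")$slice
  maps <- vector("list", nk)
  for (b in split(seq_len(nk), ceiling(seq_len(nk) / batchSize))) {
    pr <- unetForward(model, x[, , , b, drop = FALSE],
                      training = FALSE)$prob
    for (j in seq_along(b)) maps[[b[j]]] <- pr[, , 1, j]
  }
  maps
}

#' Threshold probability maps into a stacked binary mask
#'
#' @param maps list of probability-map matrices (values in \[0, 1\]).
#' @param threshold cut in (0, 1); a voxel is foreground iff p >= threshold.
#' @return 3D integer array (h, w, nslices).
#' @export
binarizeMaps <- function(maps, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    stopWithClass("threshold must be inside (0, 1)", "hepasegContractError")
  if (is.matrix(maps)) maps <- list(maps)
  stackSlices(lapply(maps, function(m) (m >= threshold) * 1L))
}
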