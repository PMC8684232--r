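## Training procedures for the two stages. The coarse stage trains on
## jittered-box crops with pixel-wise binary cross-entropy and momentum SGD
## under a polynomial learning-rate schedule; the refinement stage trains only
## on hard examples (coarse IoU below a threshold) with per-pass click
## simulation and the loss taken on the fused output, so the head learns to
## correct exactly the mistakes users would click on.

#' Training configuration
#'
#' @slot baseLR,momentum,weightDecay optimizer scalars.
#' @slot batchSize,epochs counts.
#' @slot polyPower exponent of the polynomial learning-rate schedule.
#' @slot clickLR base learning rate of the Click stage.
#' @slot hardIoUThreshold IoU below which a sample counts as hard.
#' @slot maxJitter training-time box jitter in pixels.
#' @slot nClicksTrain total click budget simulated per training pass.
#' @slot guidanceRadius,weightRadius Gaussian radii (pixels at crop scale).
#' @slot seed training seed.
#' @export
setClass("TrainConfig",
    representation(baseLR = "numeric", momentum = "numeric",
                   weightDecay = "numeric", batchSize = "integer",
                   epochs = "integer", polyPower = "numeric",
                   clickLR = "numeric", hardIoUThreshold = "numeric",
                   maxJitter = "integer", nClicksTrain = "integer",
                   guidanceRadius = "numeric", weightRadius = "numeric",
                   seed = "integer"),
    validity = function(object) {
        msg <- character()
        if (object@baseLR <= 0) msg <- c(msg, "baseLR must be positive")
        if (object@hardIoUThreshold < 0 || object@hardIoUThreshold > 1)
            msg <- c(msg, "hardIoUThreshold must lie in [0, 1]")
        if (object@epochs < 0L) msg <- c(msg, "epochs must be >= 0")
        if (length(msg)) msg else TRUE
    })

#' Create a training configuration
#'
#' Defaults mirror the reference training recipe: SGD with base learning rate
#' 0.01, momentum 0.9, weight decay 0.0005, batch size 8, 50 epochs, a poly
#' schedule with power 0.9, Click-stage base learning rate 0.1, hard-example
#' threshold IoU 0.9 and box jitter up to 30 px. The Gaussian radii default to
#' 40 px guidance / 120 px weight at a 256 px crop and are scaled
#' proportionally to other crop sizes unless given explicitly.
#'
#' @param baseLR,momentum,weightDecay,batchSize,epochs,polyPower,clickLR
#'   optimizer and schedule scalars (see slots).
#' @param hardIoUThreshold hard-example mining threshold.
#' @param maxJitter box jitter in pixels.
#' @param nClicksTrain click budget per training pass.
#' @param guidanceRadius,weightRadius Gaussian radii in pixels; \code{NULL}
#'   scales the 40/120 px defaults to the model's crop size.
#' @param seed training seed.
#' @param cropSize crop size used to scale default radii.
#' @return A \linkS4class{TrainConfig}.
#' @export
trainConfig <- function(baseLR = 0.01, momentum = 0.9, weightDecay = 5e-4,
                        batchSize = 8L, epochs = 50L, polyPower = 0.9,
                        clickLR = 0.1, hardIoUThreshold = 0.9,
                        maxJitter = 30L, nClicksTrain = 3L,
                        guidanceRadius = NULL, weightRadius = NULL,
                        seed = 1L, cropSize = 96L) {
    if (is.null(guidanceRadius)) guidanceRadius <- 40 * cropSize / 256
    if (is.null(weightRadius)) weightRadius <- 3 * guidanceRadius
    new("TrainConfig", baseLR = baseLR, momentum = momentum,
        weightDecay = weightDecay, batchSize = as.integer(batchSize),
        epochs = as.integer(epochs), polyPower = polyPower, clickLR = clickLR,
        hardIoUThreshold = hardIoUThreshold, maxJitter = as.integer(maxJitter),
        nClicksTrain = as.integer(nClicksTrain),
        guidanceRadius = guidanceRadius, weightRadius = weightRadius,
        seed = as.integer(seed))
}

#' Polynomial learning-rate schedule
#'
#' \code{lr = baseLR * (1 - iter / maxIter)^power}: equals the base rate at
#' iteration 0, decays strictly monotonically for positive power, and reaches
#' 0 at the final iteration.
#'
#' @param baseLR base learning rate.
#' @param iter current iteration, \code{0 <= iter <= maxIter}.
#' @param maxIter total number of iterations (> 0).
#' @param power decay exponent (default 0.9).
#' @return The scheduled learning rate.
#' @examples
#' polyLR(0.01, 0, 100)    # 0.01
#' polyLR(0.01, 100, 100)  # 0
#' @export
polyLR <- function(baseLR, iter, maxIter, power = 0.9) {
    if (maxIter <= 0) stop("maxIter must be positive")
    if (iter < 0 || iter > maxIter) stop("iter must lie in [0, maxIter]")
    baseLR * (1 - iter / maxIter)^power
}

## Prepare one training/eval crop: jitter the tight box (optionally), crop
## image and mask, resize both to the square crop size. Image values in
## [0, 1]; the mask is re-thresholded after resampling.
.prepareCrop <- function(image, mask, cropSize, maxJitter = 0L) {
    box <- tightBbox(mask)
    if (maxJitter > 0L)
        box <- jitterBox(box, maxJitter, extent = dim(mask))
    x <- resizeBilinear(cropBox(image, box) / 255, c(cropSize, cropSize))
    gt <- .resizeMask(cropBox(mask, box), c(cropSize, cropSize))
    list(x = x, gt = gt, box = box)
}

#' Train the coarse (SBox) stage
#'
#' Per sample and epoch: the tight box of the ground-truth mask is jittered
#' by up to \code{tc@maxJitter} px per edge (simulating the looseness of a
#' user-drawn surrounding box), the crop is resized to the model's crop size,
#' and the coarse logits are scored with pixel-wise binary cross-entropy
#' against the resampled mask. Updates use momentum SGD with weight decay
#' under a polynomial learning-rate schedule stepped once per batch. Fully
#' deterministic given \code{tc@seed}.
#'
#' @param dataset list of samples, each a list with \code{image}
#'   (H x W x 3 array, 0-255) and \code{mask} (binary matrix).
#' @param model an initialized \linkS4class{SegModel}.
#' @param tc a \linkS4class{TrainConfig}.
#' @param valDataset optional held-out samples for a per-epoch mean IoU.
#' @param verbose print a line per epoch.
#' @return List with the trained \code{model} and a \code{history} containing
#'   per-epoch mean loss, validation IoU and the full learning-rate trace.
#' @export
trainSBox <- function(dataset, model, tc, valDataset = NULL, verbose = FALSE) {
    if (length(dataset) == 0L) stop("dataset is empty")
    set.seed(tc@seed)
    p <- model@params
    cfg <- model@config
    vel <- zeroLike(p[c("encoder", "context", "sbox")])
    nBatches <- max(1L, ceiling(length(dataset) / tc@batchSize))
    maxIter <- max(1L, tc@epochs * nBatches)
    iter <- 0L
    lrTrace <- numeric(0)
    epochLoss <- numeric(0)
    valIoU <- numeric(0)
    for (epoch in seq_len(tc@epochs)) {
        ord <- sample.int(length(dataset))
        losses <- numeric(0)
        for (b in seq_len(nBatches)) {
            idx <- ord[((b - 1L) * tc@batchSize + 1L):min(b * tc@batchSize,
                                                          length(dataset))]
            idx <- idx[!is.na(idx)]
            gacc <- NULL
            bloss <- 0
            for (i in idx) {
                s <- dataset[[i]]
                cr <- .prepareCrop(s$image, s$mask, cfg@cropSize, tc@maxJitter)
                enc <- .encForward(p$encoder, cr$x, cfg)
                ctx <- .ctxForward(p$context, enc$high, cfg)
                head <- .sboxHeadForward(p$sbox, enc$low, ctx$y, cfg@cropSize)
                l <- bceWithLogits(head$logits, cr$gt)
                bloss <- bloss + l$loss
                hb <- .sboxHeadBackward(l$grad, p$sbox, head$cache)
                cb <- .ctxBackward(hb$dctx, p$context, ctx$cache, cfg)
                eb <- .encBackward(hb$dlow, cb$dhigh, p$encoder, enc$cache)
                g <- list(encoder = eb, context = cb$grad, sbox = hb$grad)
                gacc <- if (is.null(gacc)) g else addParams(gacc, g)
            }
            gacc <- scaleParams(gacc, 1 / length(idx))
            lr <- polyLR(tc@baseLR, iter, maxIter, tc@polyPower)
            lrTrace <- c(lrTrace, lr)
            upd <- sgdStep(p[c("encoder", "context", "sbox")], gacc, vel,
                           lr, tc@momentum, tc@weightDecay)
            p[c("encoder", "context", "sbox")] <- upd$p
            vel <- upd$v
            iter <- iter + 1L
            losses <- c(losses, bloss / length(idx))
        }
        epochLoss <- c(epochLoss, mean(losses))
        model@params <- p
        valIoU <- c(valIoU, if (is.null(valDataset)) NA_real_ else
            mean(.datasetIoUs(model, valDataset)))
        if (verbose)
            message(sprintf("epoch %d  lr %.5f  loss %.4f  val_iou %s",
                            epoch, lrTrace[length(lrTrace)],
                            epochLoss[epoch],
                            ifelse(is.na(valIoU[epoch]), "-",
                                   sprintf("%.4f", valIoU[epoch]))))
    }
    model@params <- p
    list(model = model,
         history = list(loss = epochLoss, valIoU = valIoU, lrTrace = lrTrace))
}

## Deterministic coarse-stage IoU of each sample on its tight-box crop.
.datasetIoUs <- function(model, dataset) {
    vapply(dataset, function(s) {
        cr <- .prepareCrop(s$image, s$mask, model@config@cropSize, 0L)
        pred <- binarize(sboxForward(model, cr$x)$logits)
        m <- maskMetrics(pred, cr$gt)
        m@iou
    }, 0)
}

#' Mine hard examples for the refinement stage
#'
#' Returns the samples whose coarse segmentation (tight box, no jitter,
#' logits binarized at 0) attains an IoU below the threshold against ground
#' truth; these are the objects the Click stage is trained on.
#'
#' @param model a trained \linkS4class{SegModel}.
#' @param dataset list of (image, mask) samples.
#' @param threshold IoU threshold (default 0.9).
#' @return List with \code{subset} (the hard samples), \code{indices} and the
#'   per-sample \code{iou} vector over the full dataset.
#' @export
mineHardExamples <- function(model, dataset, threshold = 0.9) {
    ious <- .datasetIoUs(model, dataset)
    sel <- which(ious < threshold)
    list(subset = dataset[sel], indices = sel, iou = ious)
}

#' Train the refinement (Click) stage
#'
#' The coarse stage is frozen. Per sample and pass: run the frozen coarse
#' forward to obtain logits B and the cached context features; compute the
#' false-positive and false-negative sets against ground truth; sample a
#' click budget from them (resampled every pass); encode the clicks as
#' Gaussian guidance channels; run the Click head to obtain C; build the
#' polarity-blind weight map W; fuse \code{F = W*C + B}; score sigmoid(F)
#' with pixel-wise binary cross-entropy and update only the Click-head
#' parameters (base learning rate \code{tc@clickLR}, same poly schedule).
#' Deterministic given \code{tc@seed}.
#'
#' @param hardSubset non-empty list of hard (image, mask) samples.
#' @param model a trained \linkS4class{SegModel} (coarse stage frozen).
#' @param tc a \linkS4class{TrainConfig}; \code{epochs} counts Click passes.
#' @param verbose print a line per epoch.
#' @return List with the updated \code{model} (only \code{params$click}
#'   changed) and a \code{history} as in \code{\link{trainSBox}}.
#' @export
trainClick <- function(hardSubset, model, tc, verbose = FALSE) {
    if (length(hardSubset) == 0L) stop("hard subset is empty")
    set.seed(tc@seed + 1L)
    cfg <- model@config
    pClick <- model@params$click
    vel <- zeroLike(pClick)
    nBatches <- max(1L, ceiling(length(hardSubset) / tc@batchSize))
    maxIter <- max(1L, tc@epochs * nBatches)
    iter <- 0L
    lrTrace <- numeric(0)
    epochLoss <- numeric(0)
    shape <- c(cfg@cropSize, cfg@cropSize)
    for (epoch in seq_len(tc@epochs)) {
        ord <- sample.int(length(hardSubset))
        losses <- numeric(0)
        for (b in seq_len(nBatches)) {
            idx <- ord[((b - 1L) * tc@batchSize + 1L):min(b * tc@batchSize,
                                                          length(hardSubset))]
            idx <- idx[!is.na(idx)]
            gacc <- NULL
            bloss <- 0
            for (i in idx) {
                s <- hardSubset[[i]]
                cr <- .prepareCrop(s$image, s$mask, cfg@cropSize, tc@maxJitter)
                fw <- sboxForward(model, cr$x)
                predB <- binarize(fw$logits)
                cs <- sampleClickBudget(predB, cr$gt, tc@nClicksTrain)
                gm <- encodeClicks(cs, tc@guidanceRadius, shape)
                wm <- weightMap(cs, tc@weightRadius, shape)
                head <- .clickHeadForward(pClick, fw$ctx, gm@g1, gm@g2,
                                          cfg@cropSize)
                f <- fuseLogits(fw$logits, head$logits, wm@w)
                l <- bceWithLogits(f, cr$gt)
                bloss <- bloss + l$loss
                dC <- l$grad * wm@w      # dF/dC = W elementwise
                hb <- .clickHeadBackward(dC, pClick, head$cache)
                gacc <- if (is.null(gacc)) hb$grad else addParams(gacc, hb$grad)
            }
            gacc <- scaleParams(gacc, 1 / length(idx))
            lr <- polyLR(tc@clickLR, iter, maxIter, tc@polyPower)
            lrTrace <- c(lrTrace, lr)
            upd <- sgdStep(pClick, gacc, vel, lr, tc@momentum, tc@weightDecay)
            pClick <- upd$p
            vel <- upd$v
            iter <- iter + 1L
            losses <- c(losses, bloss / length(idx))
        }
        epochLoss <- c(epochLoss, mean(losses))
        if (verbose)
            message(sprintf("click epoch %d  lr %.5f  loss %.4f",
                            epoch, lrTrace[length(lrTrace)], epochLoss[epoch]))
    }
    model@params$click <- pClick
    list(model = model,
         history = list(loss = epochLoss, valIoU = rep(NA_real_, tc@epochs),
                        lrTrace = lrTrace))
}
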