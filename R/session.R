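## Interactive sessions and the batch evaluation protocols.

#' Interactive refinement session state
#'
#' Tracks one surrounding-box session: the full-frame image, the box, the
#' accumulated clicks, the cached context features (the encoder runs exactly
#' once per session), the current coarse/refined/fused logit triple, and the
#' per-step metrics history when ground truth is available.
#'
#' @slot image full-frame H x W x 3 array (0-255).
#' @slot box the \linkS4class{SurroundingBox}.
#' @slot model the \linkS4class{SegModel} in use.
#' @slot clicks accumulated \linkS4class{ClickSet} in crop coordinates.
#' @slot ctx cached context feature grid.
#' @slot triple current \linkS4class{SegmentationTriple}.
#' @slot gt optional ground-truth crop (binary matrix at crop resolution;
#'   0 x 0 when absent).
#' @slot history data.frame of per-step metrics (step 0 = coarse result).
#' @slot encoderPasses number of encoder forward passes performed.
#' @slot guidanceRadius,weightRadius Gaussian radii used for refinement.
#' @export
setClass("SessionState",
    representation(image = "array", box = "SurroundingBox", model = "SegModel",
                   clicks = "ClickSet", ctx = "array",
                   triple = "SegmentationTriple", gt = "matrix",
                   history = "data.frame", encoderPasses = "integer",
                   guidanceRadius = "numeric", weightRadius = "numeric"))

setMethod("show", "SessionState", function(object) {
    nc <- nClicks(object@clicks)
    cat(sprintf(paste0("SessionState: box %dx%d px, %d positive / %d negative",
                       " click(s), %d refinement step(s)\n"),
        object@box@bottom - object@box@top, object@box@right - object@box@left,
        nc["positive"], nc["negative"], nrow(object@history) - 1L))
})

.sessionMetricsRow <- function(step, nclicks, logits, gt) {
    if (length(gt) == 0L)
        return(data.frame(step = step, clicks = nclicks, acc = NA_real_,
                          sen = NA_real_, spe = NA_real_, dic = NA_real_,
                          iou = NA_real_))
    m <- maskMetrics(binarize(logits), gt)
    data.frame(step = step, clicks = nclicks, acc = m@acc, sen = m@sen,
               spe = m@spe, dic = m@dic, iou = m@iou)
}

#' Start an interactive refinement session
#'
#' Crops the image to the surrounding box, resizes to the model's crop size,
#' runs the coarse stage once (caching the context features for all later
#' refinement steps) and records step-0 metrics when ground truth is given.
#' With no clicks the fused output is bit-identical to the coarse output.
#'
#' @param image full-frame H x W x 3 array (0-255).
#' @param box a \linkS4class{SurroundingBox} inside the image.
#' @param model a trained \linkS4class{SegModel}.
#' @param gt optional full-frame binary ground-truth mask.
#' @param guidanceRadius,weightRadius Gaussian radii in crop pixels;
#'   \code{NULL} scales the 40/120 px (at 256 crop) defaults to the crop size.
#' @return A \linkS4class{SessionState}.
#' @export
refineSession <- function(image, box, model, gt = NULL,
                          guidanceRadius = NULL, weightRadius = NULL) {
    cs <- model@config@cropSize
    if (is.null(guidanceRadius)) guidanceRadius <- 40 * cs / 256
    if (is.null(weightRadius)) weightRadius <- 3 * guidanceRadius
    x <- resizeBilinear(cropBox(image, box) / 255, c(cs, cs))
    fw <- sboxForward(model, x)
    gtCrop <- if (is.null(gt)) matrix(0, 0L, 0L)
              else .resizeMask(cropBox(gt, box), c(cs, cs))
    zero <- matrix(0, cs, cs)
    triple <- new("SegmentationTriple", b = fw$logits, c = zero,
                  f = fuseLogits(fw$logits, zero, zero), w = zero)
    new("SessionState", image = image, box = box, model = model,
        clicks = clickSet(), ctx = fw$ctx, triple = triple, gt = gtCrop,
        history = .sessionMetricsRow(0L, 0L, triple@f, gtCrop),
        encoderPasses = 1L, guidanceRadius = guidanceRadius,
        weightRadius = weightRadius)
}

#' Add user clicks to a session and refine
#'
#' Appends the clicks to the accumulated set, re-encodes the guidance
#' channels, runs the Click head on the cached context features (no second
#' encoder pass), rebuilds the weight map and the fused logits, and appends a
#' metrics row when ground truth is available.
#'
#' @param session a \linkS4class{SessionState}.
#' @param clicks a \linkS4class{ClickSet} in crop coordinates.
#' @return The updated \linkS4class{SessionState}.
#' @export
addClicks <- function(session, clicks) {
    cs <- session@model@config@cropSize
    all_ <- rbind(clicks@positives, clicks@negatives)
    if (nrow(all_) && (max(all_[, 1]) >= cs || max(all_[, 2]) >= cs))
        stop("clicks must lie inside the crop")
    merged <- mergeClicks(session@clicks, clicks)
    gm <- encodeClicks(merged, session@guidanceRadius, c(cs, cs))
    wm <- weightMap(merged, session@weightRadius, c(cs, cs))
    cLogits <- clickForward(session@model, session@ctx, gm)
    f <- fuseLogits(session@triple@b, cLogits, wm@w)
    session@clicks <- merged
    session@triple <- new("SegmentationTriple", b = session@triple@b,
                          c = cLogits, f = f, w = wm@w)
    session@history <- rbind(session@history,
        .sessionMetricsRow(nrow(session@history), sum(nClicks(merged)),
                           f, session@gt))
    session
}

#' Final full-frame mask of a session
#'
#' Binarizes the fused logits, resamples them back to the box dimensions and
#' pastes into an all-background full frame: pixels outside the surrounding
#' box are background by construction.
#'
#' @param session a \linkS4class{SessionState}.
#' @return Full-frame binary 0/1 matrix.
#' @export
sessionMask <- function(session) {
    box <- session@box
    bh <- box@bottom - box@top; bw <- box@right - box@left
    patch <- .resizeMask(binarize(session@triple@f), c(bh, bw))
    frame <- matrix(0, dim(session@image)[1], dim(session@image)[2])
    pasteBox(frame, patch, box)
}

#' Batch evaluation at a fixed click budget
#'
#' For every sample: take the tight box (jittered by \code{evalJitter} px if
#' requested; 0 by default for deterministic reports), run the coarse stage
#' and record its metrics; then sample \code{nClicks} clicks from the coarse
#' error sets (the same strategy used in training), refine once, and record
#' the fused metrics. Metrics are computed over the cropped region at crop
#' resolution, the frame both stages operate in.
#'
#' @param model a trained \linkS4class{SegModel}.
#' @param dataset list of (image, mask) samples.
#' @param nClicks click budget per sample.
#' @param seed RNG seed for click sampling (and jitter, if enabled).
#' @param evalJitter evaluation-time box jitter in pixels (default 0).
#' @param guidanceRadius,weightRadius Gaussian radii (defaults as in
#'   \code{\link{refineSession}}).
#' @return List with \code{perSample} (data.frame: sample, base and refined
#'   metrics, exact deltas), \code{means} and \code{deltas} (named vectors).
#' @export
evaluateDataset <- function(model, dataset, nClicks = 2L, seed = 1L,
                            evalJitter = 0L, guidanceRadius = NULL,
                            weightRadius = NULL) {
    if (length(dataset) == 0L) stop("dataset is empty")
    set.seed(seed)
    cs <- model@config@cropSize
    if (is.null(guidanceRadius)) guidanceRadius <- 40 * cs / 256
    if (is.null(weightRadius)) weightRadius <- 3 * guidanceRadius
    shape <- c(cs, cs)
    rows <- vector("list", length(dataset))
    for (i in seq_along(dataset)) {
        s <- dataset[[i]]
        cr <- .prepareCrop(s$image, s$mask, cs, evalJitter)
        fw <- sboxForward(model, cr$x)
        predB <- binarize(fw$logits)
        base <- maskMetrics(predB, cr$gt)
        csel <- sampleClickBudget(predB, cr$gt, nClicks)
        nUsed <- nrow(csel@positives) + nrow(csel@negatives)
        if (nUsed > 0L) {
            gm <- encodeClicks(csel, guidanceRadius, shape)
            wm <- weightMap(csel, weightRadius, shape)
            f <- fuseLogits(fw$logits, clickForward(model, fw$ctx, gm), wm@w)
        } else f <- fw$logits
        ref <- maskMetrics(binarize(f), cr$gt)
        b <- metricsVector(base); r <- metricsVector(ref)
        rows[[i]] <- data.frame(sample = i, t(setNames(b, paste0("base_", names(b)))),
                                t(setNames(r, paste0("refined_", names(r)))),
                                t(setNames(r - b, paste0("delta_", names(b)))),
                                clicks = nUsed)
    }
    perSample <- do.call(rbind, rows)
    means <- colMeans(perSample[, -1, drop = FALSE], na.rm = TRUE)
    list(perSample = perSample, means = means,
         deltas = means[grep("^delta_", names(means))])
}

#' Clicks needed to reach a target IoU
#'
#' Interactive-cost protocol: drawing the surrounding box is counted as 2
#' clicks. Per sample, if the coarse IoU already meets the target the sample
#' costs 2 clicks; otherwise one click is sampled per step from the error
#' sets of the current fused prediction, the session is refined after each,
#' until the target is met or \code{maxClicks} refinement clicks have been
#' spent. Samples still below the target at the budget are censored at
#' \code{2 + maxClicks} and flagged rather than silently averaged.
#'
#' @param model a trained \linkS4class{SegModel}.
#' @param dataset list of (image, mask) samples.
#' @param targetIoU target IoU in (0, 1].
#' @param maxClicks maximum refinement clicks per sample.
#' @param seed RNG seed.
#' @param guidanceRadius,weightRadius Gaussian radii (defaults as in
#'   \code{\link{refineSession}}).
#' @return List with \code{meanClicks}, per-sample \code{clicks} and
#'   \code{censored} flags, and the per-sample final \code{iou}.
#' @export
clicksToTarget <- function(model, dataset, targetIoU, maxClicks = 10L,
                           seed = 1L, guidanceRadius = NULL,
                           weightRadius = NULL) {
    if (targetIoU <= 0 || targetIoU > 1) stop("targetIoU must lie in (0, 1]")
    if (maxClicks < 0) stop("maxClicks must be >= 0")
    set.seed(seed)
    cs <- model@config@cropSize
    if (is.null(guidanceRadius)) guidanceRadius <- 40 * cs / 256
    if (is.null(weightRadius)) weightRadius <- 3 * guidanceRadius
    shape <- c(cs, cs)
    clicksUsed <- integer(length(dataset))
    censored <- logical(length(dataset))
    finalIoU <- numeric(length(dataset))
    for (i in seq_along(dataset)) {
        s <- dataset[[i]]
        cr <- .prepareCrop(s$image, s$mask, cs, 0L)
        fw <- sboxForward(model, cr$x)
        f <- fw$logits
        cset <- clickSet()
        iou <- maskMetrics(binarize(f), cr$gt)@iou
        extra <- 0L
        while (!is.na(iou) && iou < targetIoU && extra < maxClicks) {
            one <- sampleClickBudget(binarize(f), cr$gt, 1L)
            if (sum(nClicks(one)) == 0L) break
            cset <- mergeClicks(cset, one)
            gm <- encodeClicks(cset, guidanceRadius, shape)
            wm <- weightMap(cset, weightRadius, shape)
            f <- fuseLogits(fw$logits, clickForward(model, fw$ctx, gm), wm@w)
            iou <- maskMetrics(binarize(f), cr$gt)@iou
            extra <- extra + 1L
        }
        clicksUsed[i] <- 2L + extra
        censored[i] <- is.na(iou) || iou < targetIoU
        finalIoU[i] <- iou
    }
    list(meanClicks = mean(clicksUsed), clicks = clicksUsed,
         censored = censored, iou = finalIoU)
}

#' Ablation harness over global-context extractors
#'
#' Trains the coarse stage (and optionally the Click stage) once per context
#' variant under identical seeds and data, then evaluates each, emitting one
#' comparison row per variant.
#'
#' @param dataset training samples.
#' @param testDataset evaluation samples.
#' @param variants character vector from \code{c("aspp", "psp", "naive")}.
#' @param mc a \linkS4class{ModelConfig} (its context slot is overridden).
#' @param tc a \linkS4class{TrainConfig}.
#' @param withClick also train the Click stage and report fused IoU.
#' @param clickEpochs Click-stage epochs when \code{withClick}.
#' @param nClicks click budget for the fused evaluation.
#' @param verbose print progress.
#' @return data.frame with one row per variant: sbox_iou and (when
#'   \code{withClick}) fused_iou.
#' @export
ablationHarness <- function(dataset, testDataset, variants, mc, tc,
                            withClick = TRUE, clickEpochs = NULL,
                            nClicks = 2L, verbose = FALSE) {
    if (length(variants) < 1L) stop("at least one variant is required")
    rows <- vector("list", length(variants))
    for (k in seq_along(variants)) {
        cfg <- mc
        cfg@context <- variants[k]
        validObject(cfg)
        model <- initModel(cfg)
        tr <- trainSBox(dataset, model, tc, verbose = verbose)
        ev <- evaluateDataset(tr$model, testDataset, nClicks = 0L, seed = tc@seed)
        sboxIoU <- unname(ev$means["base_iou"])
        fusedIoU <- NA_real_
        if (withClick) {
            mined <- mineHardExamples(tr$model, dataset, tc@hardIoUThreshold)
            if (length(mined$subset) > 0L) {
                tcClick <- tc
                if (!is.null(clickEpochs)) tcClick@epochs <- as.integer(clickEpochs)
                trc <- trainClick(mined$subset, tr$model, tcClick)
                evc <- evaluateDataset(trc$model, testDataset, nClicks = nClicks,
                                       seed = tc@seed)
                fusedIoU <- unname(evc$means["refined_iou"])
            } else fusedIoU <- sboxIoU
        }
        rows[[k]] <- data.frame(context = variants[k], sbox_iou = sboxIoU,
                                fused_iou = fusedIoU)
        if (verbose)
            message(sprintf("variant %s: sbox IoU %.4f, fused IoU %s",
                            variants[k], sboxIoU,
                            ifelse(is.na(fusedIoU), "-",
                                   sprintf("%.4f", fusedIoU))))
    }
    do.call(rbind, rows)
}
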