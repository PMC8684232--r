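## The two network stages. A shared convolutional encoder yields a shallow,
## high-resolution feature grid (stride 4) and a deep, context-rich grid
## (stride 16). A pluggable global-context extractor (aspp / psp / naive)
## enriches the deep grid. The SBox head decodes both grids into coarse
## segmentation logits; the Click head consumes the context features plus the
## two Gaussian guidance channels and emits refinement logits. The encoder is
## deliberately compact (well under 100k parameters at the default widths) so
## both stages train on a single CPU; an application wanting a large
## pretrained backbone only needs to reproduce the two-grid feature contract.

#' Model configuration
#'
#' @slot cropSize square crop side in pixels, divisible by 16.
#' @slot widths integer encoder channel widths at strides 2, 4, 8, 16.
#' @slot cLowReduced channels the shallow features are reduced to (1x1 conv).
#' @slot cContext channels emitted by the global-context extractor.
#' @slot cRefine channels of the SBox 3x3 refinement convolution.
#' @slot cClick channels of the Click head.
#' @slot context global-context extractor: "aspp", "psp" or "naive".
#' @slot seed parameter-initialization seed.
#' @export
setClass("ModelConfig",
    representation(cropSize = "integer", widths = "integer",
                   cLowReduced = "integer", cContext = "integer",
                   cRefine = "integer", cClick = "integer",
                   context = "character", seed = "integer"),
    validity = function(object) {
        msg <- character()
        if (object@cropSize %% 16L != 0L)
            msg <- c(msg, "cropSize must be divisible by 16")
        if (length(object@widths) != 4L || any(object@widths < 1L))
            msg <- c(msg, "widths must be four positive channel counts")
        if (!object@context %in% c("aspp", "psp", "naive"))
            msg <- c(msg, "context must be aspp, psp or naive")
        if (length(msg)) msg else TRUE
    })

#' Create a model configuration
#'
#' @param cropSize crop side in pixels (divisible by 16).
#' @param widths encoder channel widths at strides 2/4/8/16.
#' @param cLowReduced,cContext,cRefine,cClick head channel counts.
#' @param context global-context extractor kind: \code{"aspp"}, \code{"psp"}
#'   or \code{"naive"}.
#' @param seed parameter-initialization seed.
#' @return A \linkS4class{ModelConfig}.
#' @export
modelConfig <- function(cropSize = 96L, widths = c(8L, 16L, 24L, 32L),
                        cLowReduced = 8L, cContext = 32L, cRefine = 16L,
                        cClick = 16L, context = "aspp", seed = 1L) {
    new("ModelConfig", cropSize = as.integer(cropSize),
        widths = as.integer(widths), cLowReduced = as.integer(cLowReduced),
        cContext = as.integer(cContext), cRefine = as.integer(cRefine),
        cClick = as.integer(cClick), context = context, seed = as.integer(seed))
}

#' Two-stage segmentation model
#'
#' Holds the parameters of the encoder, the global-context extractor, the
#' SBox decoding head and the Click refinement head, plus the configuration
#' they were built with.
#'
#' @slot config a \linkS4class{ModelConfig}.
#' @slot params nested parameter list (encoder / context / sbox / click).
#' @export
setClass("SegModel", representation(config = "ModelConfig", params = "list"))

setMethod("show", "SegModel", function(object) {
    cat(sprintf(
        "SegModel: crop %dx%d, context '%s', %d parameters (%d in Click head)\n",
        object@config@cropSize, object@config@cropSize, object@config@context,
        countModelParams(object), countParams(object@params$click)))
})

.initConv <- function(kh, kw, cin, cout) {
    list(w = array(rnorm(kh * kw * cin * cout) * sqrt(2 / (kh * kw * cin)),
                   c(kh, kw, cin, cout)),
         b = rep(0, cout))
}

.initContextParams <- function(cfg) {
    w4 <- cfg@widths[4]; cc <- cfg@cContext
    switch(cfg@context,
        naive = list(conv = .initConv(3L, 3L, w4, cc)),
        aspp = {
            cb <- max(4L, cc %/% 4L)
            list(br1 = .initConv(3L, 3L, w4, cb),
                 br2 = .initConv(3L, 3L, w4, cb),
                 br3 = .initConv(3L, 3L, w4, cb),
                 gp  = .initConv(1L, 1L, w4, cb),
                 proj = .initConv(1L, 1L, 4L * cb, cc))
        },
        psp = {
            cp <- max(4L, cc %/% 4L)
            list(p1 = .initConv(1L, 1L, w4, cp),
                 p2 = .initConv(1L, 1L, w4, cp),
                 p3 = .initConv(1L, 1L, w4, cp),
                 p6 = .initConv(1L, 1L, w4, cp),
                 proj = .initConv(1L, 1L, w4 + 4L * cp, cc))
        })
}

#' Initialize a two-stage segmentation model
#'
#' Parameters are He-initialized deterministically from \code{config@seed};
#' two constructions from the same configuration are bit-identical.
#'
#' @param config a \linkS4class{ModelConfig}.
#' @return An untrained \linkS4class{SegModel}.
#' @export
initModel <- function(config) {
    set.seed(config@seed)
    w <- config@widths
    params <- list(
        encoder = list(conv1 = .initConv(3L, 3L, 3L, w[1]),
                       conv2 = .initConv(3L, 3L, w[1], w[2]),
                       conv3 = .initConv(3L, 3L, w[2], w[3]),
                       conv4 = .initConv(3L, 3L, w[3], w[4])),
        context = .initContextParams(config),
        sbox = list(lowred = .initConv(1L, 1L, w[2], config@cLowReduced),
                    refine = .initConv(3L, 3L, config@cLowReduced + config@cContext,
                                       config@cRefine),
                    proj = .initConv(1L, 1L, config@cRefine, 1L)),
        click = list(ctxred = .initConv(1L, 1L, config@cContext, config@cClick),
                     refine = .initConv(3L, 3L, config@cClick + 2L, config@cClick),
                     proj = .initConv(1L, 1L, config@cClick, 1L)))
    new("SegModel", config = config, params = params)
}

#' Total number of model parameters
#'
#' @param model a \linkS4class{SegModel}.
#' @return Integer parameter count over all four blocks.
#' @export
countModelParams <- function(model) countParams(model@params)

## ---- encoder ---------------------------------------------------------------

#' Encoder forward pass
#'
#' Four stride-2 3x3 convolutions with ReLU; features are tapped after the
#' second (stride 4, shallow) and fourth (stride 16, deep) stages. Input
#' values are expected in [0, 1] (the crop pipeline maps 8-bit RGB to
#' \code{v / 255}) and are centred internally.
#'
#' @param model a \linkS4class{SegModel}.
#' @param x cropSize x cropSize x 3 array in [0, 1].
#' @return List with \code{low} (H/4 grid) and \code{high} (H/16 grid).
#' @export
encoderForward <- function(model, x) {
    fw <- .encForward(model@params$encoder, x, model@config)
    list(low = fw$low, high = fw$high)
}

.encForward <- function(p, x, cfg) {
    if (!identical(dim(x)[1:2], rep(cfg@cropSize, 2L)))
        stop("input patch must be cropSize x cropSize")
    x <- x - 0.5
    c1 <- convForward(x, p$conv1, stride = 2L, pad = 1L)
    r1 <- reluForward(c1$y)
    c2 <- convForward(r1$y, p$conv2, stride = 2L, pad = 1L)
    r2 <- reluForward(c2$y)
    c3 <- convForward(r2$y, p$conv3, stride = 2L, pad = 1L)
    r3 <- reluForward(c3$y)
    c4 <- convForward(r3$y, p$conv4, stride = 2L, pad = 1L)
    r4 <- reluForward(c4$y)
    list(low = r2$y, high = r4$y,
         cache = list(c1 = c1, r1 = r1, c2 = c2, r2 = r2,
                      c3 = c3, r3 = r3, c4 = c4, r4 = r4))
}

.encBackward <- function(dlow, dhigh, p, cache) {
    g <- reluBackward(dhigh, cache$r4$cache)
    b4 <- convBackward(g, p$conv4, cache$c4$cache)
    g <- reluBackward(b4$dx, cache$r3$cache)
    b3 <- convBackward(g, p$conv3, cache$c3$cache)
    g <- reluBackward(b3$dx + dlow, cache$r2$cache)
    b2 <- convBackward(g, p$conv2, cache$c2$cache)
    g <- reluBackward(b2$dx, cache$r1$cache)
    b1 <- convBackward(g, p$conv1, cache$c1$cache, needDx = FALSE)
    list(conv1 = b1$grad, conv2 = b2$grad, conv3 = b3$grad, conv4 = b4$grad)
}

## ---- global-context extractors ---------------------------------------------

#' Global-context extraction on the deep feature grid
#'
#' Three interchangeable variants behind one interface: \code{aspp} (parallel
#' dilated 3x3 convolutions at rates 1/2/4 plus a global-pooled branch,
#' concatenated and 1x1-projected), \code{psp} (features pooled to 1/2/3/6
#' pyramid grids, projected, upsampled, concatenated with the input and
#' 1x1-projected) and \code{naive} (a single 3x3 convolution). All preserve
#' spatial size.
#'
#' @param model a \linkS4class{SegModel}.
#' @param high H/16 feature grid from \code{\link{encoderForward}}.
#' @return Context feature grid of the same spatial size.
#' @export
contextExtract <- function(model, high) {
    .ctxForward(model@params$context, high, model@config)$y
}

.ctxForward <- function(p, high, cfg) {
    d <- dim(high)
    switch(cfg@context,
        naive = {
            cv <- convForward(high, p$conv, pad = 1L)
            rl <- reluForward(cv$y)
            list(y = rl$y, cache = list(cv = cv, rl = rl))
        },
        aspp = {
            rates <- c(1L, 2L, 4L)
            brs <- vector("list", 3L)
            for (k in 1:3) {
                cv <- convForward(high, p[[paste0("br", k)]],
                                  pad = rates[k], dilation = rates[k])
                rl <- reluForward(cv$y)
                brs[[k]] <- list(cv = cv, rl = rl)
            }
            pl <- adaptivePoolForward(high, 1L)
            gc_ <- convForward(pl$y, p$gp)
            gr <- reluForward(gc_$y)
            cb <- dim(gr$y)[3]
            bc <- array(rep(gr$y, each = d[1] * d[2]), c(d[1], d[2], cb))
            cat_ <- catChannels(brs[[1]]$rl$y, brs[[2]]$rl$y, brs[[3]]$rl$y, bc)
            pj <- convForward(cat_, p$proj)
            rl <- reluForward(pj$y)
            list(y = rl$y, cache = list(brs = brs, pl = pl, gc = gc_, gr = gr,
                                        cb = cb, d = d, pj = pj, rl = rl))
        },
        psp = {
            grids <- c(1L, 2L, 3L, 6L)
            nms <- c("p1", "p2", "p3", "p6")
            brs <- vector("list", 4L)
            for (k in 1:4) {
                pl <- adaptivePoolForward(high, grids[k])
                cv <- convForward(pl$y, p[[nms[k]]])
                rl <- reluForward(cv$y)
                up <- resizeForward(rl$y, d[1:2])
                brs[[k]] <- list(pl = pl, cv = cv, rl = rl, up = up)
            }
            cat_ <- catChannels(high, brs[[1]]$up$y, brs[[2]]$up$y,
                                brs[[3]]$up$y, brs[[4]]$up$y)
            pj <- convForward(cat_, p$proj)
            rl <- reluForward(pj$y)
            list(y = rl$y, cache = list(brs = brs, d = d, pj = pj, rl = rl))
        })
}

.ctxBackward <- function(dy, p, cache, cfg) {
    switch(cfg@context,
        naive = {
            g <- reluBackward(dy, cache$rl$cache)
            bk <- convBackward(g, p$conv, cache$cv$cache)
            list(dhigh = bk$dx, grad = list(conv = bk$grad))
        },
        aspp = {
            rates <- c(1L, 2L, 4L)
            g <- reluBackward(dy, cache$rl$cache)
            bp <- convBackward(g, p$proj, cache$pj$cache)
            cb <- cache$cb
            parts <- splitChannels(bp$dx, rep(cb, 4L))
            grads <- list()
            dhigh <- 0
            for (k in 1:3) {
                gb <- reluBackward(parts[[k]], cache$brs[[k]]$rl$cache)
                bk <- convBackward(gb, p[[paste0("br", k)]],
                                   cache$brs[[k]]$cv$cache)
                grads[[paste0("br", k)]] <- bk$grad
                dhigh <- dhigh + bk$dx
            }
            # global branch: broadcast adjoint = sum over spatial positions
            gbc <- apply(parts[[4]], 3L, sum)
            gbc <- array(gbc, c(1L, 1L, cb))
            gg <- reluBackward(gbc, cache$gr$cache)
            bg <- convBackward(gg, p$gp, cache$gc$cache)
            grads$gp <- bg$grad
            dhigh <- dhigh + adaptivePoolBackward(bg$dx, cache$pl$cache)
            grads$proj <- bp$grad
            list(dhigh = dhigh, grad = grads)
        },
        psp = {
            nms <- c("p1", "p2", "p3", "p6")
            g <- reluBackward(dy, cache$rl$cache)
            bp <- convBackward(g, p$proj, cache$pj$cache)
            w4 <- cache$d[3]
            cp <- dim(cache$brs[[1]]$rl$y)[3]
            parts <- splitChannels(bp$dx, c(w4, rep(cp, 4L)))
            dhigh <- parts[[1]]
            grads <- list()
            for (k in 1:4) {
                gu <- resizeBackward(parts[[k + 1L]], cache$brs[[k]]$up$cache)
                gr <- reluBackward(gu, cache$brs[[k]]$rl$cache)
                bk <- convBackward(gr, p[[nms[k]]], cache$brs[[k]]$cv$cache)
                grads[[nms[k]]] <- bk$grad
                dhigh <- dhigh + adaptivePoolBackward(bk$dx, cache$brs[[k]]$pl$cache)
            }
            grads$proj <- bp$grad
            list(dhigh = dhigh, grad = grads)
        })
}

## ---- SBox head ---------------------------------------------------------------

.sboxHeadForward <- function(p, low, ctx, cropSize) {
    lr_ <- convForward(low, p$lowred)
    lrl <- reluForward(lr_$y)
    up <- resizeForward(ctx, dim(low)[1:2])
    cat_ <- catChannels(lrl$y, up$y)
    rf <- convForward(cat_, p$refine, pad = 1L)
    rl <- reluForward(rf$y)
    pj <- convForward(rl$y, p$proj)
    out <- resizeForward(pj$y, c(cropSize, cropSize))
    logits <- out$y[, , 1L]
    list(logits = logits,
         cache = list(lr = lr_, lrl = lrl, up = up, rf = rf, rl = rl,
                      pj = pj, out = out,
                      nLow = dim(lrl$y)[3], nCtx = dim(ctx)[3]))
}

.sboxHeadBackward <- function(dlogits, p, cache) {
    g <- resizeBackward(dlogits, cache$out$cache)
    bp <- convBackward(g, p$proj, cache$pj$cache)
    g <- reluBackward(bp$dx, cache$rl$cache)
    br <- convBackward(g, p$refine, cache$rf$cache)
    parts <- splitChannels(br$dx, c(cache$nLow, cache$nCtx))
    dctx <- resizeBackward(parts[[2]], cache$up$cache)
    g <- reluBackward(parts[[1]], cache$lrl$cache)
    bl <- convBackward(g, p$lowred, cache$lr$cache)
    list(dlow = bl$dx, dctx = dctx,
         grad = list(lowred = bl$grad, refine = br$grad, proj = bp$grad))
}

## ---- Click head ---------------------------------------------------------------

.clickHeadForward <- function(p, ctx, g1, g2, cropSize) {
    cr <- convForward(ctx, p$ctxred)
    crl <- reluForward(cr$y)
    fd <- dim(ctx)[1:2]
    g1s <- resizeForward(g1, fd)
    g2s <- resizeForward(g2, fd)
    cat_ <- catChannels(crl$y, g1s$y, g2s$y)
    rf <- convForward(cat_, p$refine, pad = 1L)
    rl <- reluForward(rf$y)
    pj <- convForward(rl$y, p$proj)
    out <- resizeForward(pj$y, c(cropSize, cropSize))
    list(logits = out$y[, , 1L],
         cache = list(cr = cr, crl = crl, rf = rf, rl = rl, pj = pj,
                      out = out, nRed = dim(crl$y)[3]))
}

.clickHeadBackward <- function(dlogits, p, cache) {
    g <- resizeBackward(dlogits, cache$out$cache)
    bp <- convBackward(g, p$proj, cache$pj$cache)
    g <- reluBackward(bp$dx, cache$rl$cache)
    br <- convBackward(g, p$refine, cache$rf$cache)
    # guidance channels and the frozen context features need no gradient;
    # only the reduced-context block feeds the ctxred update
    parts <- splitChannels(br$dx, c(cache$nRed, 1L, 1L))
    g <- reluBackward(parts[[1]], cache$crl$cache)
    bc <- convBackward(g, p$ctxred, cache$cr$cache, needDx = FALSE)
    list(grad = list(ctxred = bc$grad, refine = br$grad, proj = bp$grad))
}

## ---- public forward passes -----------------------------------------------

#' Coarse-stage forward pass
#'
#' Runs the encoder, the global-context extractor and the SBox decoding head
#' on a normalized crop, returning the coarse logits and the context features
#' that the Click stage reuses (so interactive refinement never needs a second
#' encoder pass).
#'
#' @param model a \linkS4class{SegModel}.
#' @param x cropSize x cropSize x 3 array in [0, 1].
#' @return List with \code{logits} (crop-resolution coarse logit matrix) and
#'   \code{ctx} (cached context feature grid).
#' @export
sboxForward <- function(model, x) {
    enc <- .encForward(model@params$encoder, x, model@config)
    ctx <- .ctxForward(model@params$context, enc$high, model@config)
    head <- .sboxHeadForward(model@params$sbox, enc$low, ctx$y,
                             model@config@cropSize)
    list(logits = head$logits, ctx = ctx$y)
}

#' Refinement-stage forward pass
#'
#' Consumes the context features cached from \code{\link{sboxForward}} plus
#' the two Gaussian guidance channels (computed at crop resolution and
#' bilinearly downsampled to the feature grid) and returns refinement logits
#' at crop resolution.
#'
#' @param model a \linkS4class{SegModel}.
#' @param ctx context feature grid from \code{\link{sboxForward}}.
#' @param gm a \linkS4class{GuidanceMaps} at crop resolution.
#' @return Crop-resolution refinement logit matrix.
#' @export
clickForward <- function(model, ctx, gm) {
    .clickHeadForward(model@params$click, ctx, gm@g1, gm@g2,
                      model@config@cropSize)$logits
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single file holding the parameters, the configuration and
#' the package version; loading validates that the configuration is complete.
#'
#' @param model a \linkS4class{SegModel}.
#' @param path checkpoint file path.
#' @export
saveModel <- function(model, path) {
    obj <- list(version = as.character(utils::packageVersion("ClickSeg")),
                config = list(cropSize = model@config@cropSize,
                              widths = model@config@widths,
                              cLowReduced = model@config@cLowReduced,
                              cContext = model@config@cContext,
                              cRefine = model@config@cRefine,
                              cClick = model@config@cClick,
                              context = model@config@context,
                              seed = model@config@seed),
                params = model@params)
    saveRDS(obj, path)
    invisible(path)
}

#' @rdname saveModel
#' @return \code{loadModel} returns the restored \linkS4class{SegModel}.
#' @export
loadModel <- function(path) {
    obj <- readRDS(path)
    need <- c("cropSize", "widths", "cLowReduced", "cContext", "cRefine",
              "cClick", "context", "seed")
    if (!all(need %in% names(obj$config)))
        stop("incompatible checkpoint: missing configuration fields")
    cfg <- do.call(modelConfig, obj$config)
    new("SegModel", config = cfg, params = obj$params)
}
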