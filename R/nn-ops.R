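## Minimal neural-network primitives: im2col convolution, ReLU, bilinear
## resampling and adaptive average pooling, each with a hand-written adjoint.
## Feature maps are H x W x C arrays; kernels are (kh, kw, Cin, Cout) arrays.
## All functions are deterministic; nothing here touches the RNG.

.as3d <- function(x) {
    if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
    x
}

convForward <- function(x, layer, stride = 1L, pad = 0L, dilation = 1L) {
    x <- .as3d(x)
    kd <- dim(layer$w)
    cols <- cpp_im2col(x, kd[1], kd[2], as.integer(stride), as.integer(pad),
                       as.integer(dilation))
    y <- cols %*% matrix(layer$w, ncol = kd[4])
    y <- y + rep(layer$b, each = nrow(y))
    effKh <- (kd[1] - 1L) * dilation + 1L
    effKw <- (kd[2] - 1L) * dilation + 1L
    hout <- (dim(x)[1] + 2L * pad - effKh) %/% stride + 1L
    wout <- (dim(x)[2] + 2L * pad - effKw) %/% stride + 1L
    dim(y) <- c(hout, wout, kd[4])
    list(y = y, cache = list(cols = cols, xdim = dim(x), kd = kd,
                             stride = stride, pad = pad, dilation = dilation))
}

convBackward <- function(gy, layer, cache, needDx = TRUE) {
    kd <- cache$kd
    gmat <- matrix(gy, ncol = kd[4])
    dw <- crossprod(cache$cols, gmat)
    dim(dw) <- kd
    db <- colSums(gmat)
    dx <- NULL
    if (needDx) {
        dcols <- gmat %*% t(matrix(layer$w, ncol = kd[4]))
        dx <- cpp_col2im(dcols, cache$xdim[1], cache$xdim[2], cache$xdim[3],
                         kd[1], kd[2], cache$stride, cache$pad, cache$dilation)
    }
    list(dx = dx, grad = list(w = dw, b = db))
}

reluForward <- function(x) list(y = pmax(x, 0), cache = x > 0)
reluBackward <- function(gy, cache) gy * cache

resizeForward <- function(x, outDim) {
    x <- .as3d(x)
    d <- dim(x)
    y <- array(0, c(outDim[1], outDim[2], d[3]))
    for (k in seq_len(d[3]))
        y[, , k] <- cpp_resize_bilinear(matrix(x[, , k], d[1], d[2]),
                                        as.integer(outDim[1]),
                                        as.integer(outDim[2]))
    list(y = y, cache = d)
}

resizeBackward <- function(gy, cache) {
    gy <- .as3d(gy)
    gx <- array(0, cache)
    d <- dim(gy)
    for (k in seq_len(cache[3]))
        gx[, , k] <- cpp_resize_bilinear_adjoint(matrix(gy[, , k], d[1], d[2]),
                                                 cache[1], cache[2])
    gx
}

## Adaptive average pooling to a g x g grid (cell bounds floor/ceil as in the
## usual adaptive-pooling convention, so g may exceed the input size).
.poolRanges <- function(n, g) {
    lo <- floor((seq_len(g) - 1L) * n / g) + 1L
    hi <- ceiling(seq_len(g) * n / g)
    cbind(lo, pmax(hi, lo))
}

adaptivePoolForward <- function(x, g) {
    x <- .as3d(x)
    d <- dim(x)
    rr <- .poolRanges(d[1], g); cc <- .poolRanges(d[2], g)
    y <- array(0, c(g, g, d[3]))
    for (i in seq_len(g)) for (j in seq_len(g)) {
        cell <- x[rr[i, 1]:rr[i, 2], cc[j, 1]:cc[j, 2], , drop = FALSE]
        y[i, j, ] <- apply(cell, 3L, mean)
    }
    list(y = y, cache = list(d = d, rr = rr, cc = cc))
}

adaptivePoolBackward <- function(gy, cache) {
    d <- cache$d; rr <- cache$rr; cc <- cache$cc
    gx <- array(0, d)
    g <- nrow(rr)
    for (i in seq_len(g)) for (j in seq_len(g)) {
        rows <- rr[i, 1]:rr[i, 2]; cols <- cc[j, 1]:cc[j, 2]
        npix <- length(rows) * length(cols)
        for (k in seq_len(d[3]))
            gx[rows, cols, k] <- gx[rows, cols, k] + gy[i, j, k] / npix
    }
    gx
}

catChannels <- function(...) {
    xs <- lapply(list(...), .as3d)
    d <- dim(xs[[1]])
    array(c(...), c(d[1], d[2], sum(vapply(xs, function(z) dim(z)[3], 0))))
}

splitChannels <- function(g, sizes) {
    out <- vector("list", length(sizes))
    at <- 0L
    for (k in seq_along(sizes)) {
        out[[k]] <- g[, , at + seq_len(sizes[k]), drop = FALSE]
        at <- at + sizes[k]
    }
    out
}

## Numerically stable pixel-wise binary cross-entropy on logits.
## Returns mean loss and gradient w.r.t. the logits.
bceWithLogits <- function(z, y) {
    n <- length(z)
    loss <- sum(pmax(z, 0) - z * y + log1p(exp(-abs(z)))) / n
    grad <- (1 / (1 + exp(-z)) - y) / n
    list(loss = loss, grad = grad)
}

## ---- nested parameter-list utilities -------------------------------------

mapParams <- function(f, p) {
    if (is.list(p)) lapply(p, mapParams, f = f) else f(p)
}

map2Params <- function(f, a, b) {
    if (is.list(a)) {
        out <- vector("list", length(a)); names(out) <- names(a)
        for (nm in names(a)) out[[nm]] <- map2Params(f, a[[nm]], b[[nm]])
        out
    } else f(a, b)
}

zeroLike <- function(p) mapParams(function(x) x * 0, p)

addParams <- function(a, b) map2Params(`+`, a, b)

scaleParams <- function(p, s) mapParams(function(x) x * s, p)

countParams <- function(p) {
    if (is.list(p)) sum(vapply(p, countParams, 0)) else length(p)
}

## One SGD-with-momentum step with decoupled L2 weight decay folded into the
## gradient (classic momentum: v <- mu v + g + wd p; p <- p - lr v).
sgdStep <- function(p, g, v, lr, momentum, weightDecay) {
    if (is.list(p)) {
        for (nm in names(p)) {
            r <- sgdStep(p[[nm]], g[[nm]], v[[nm]], lr, momentum, weightDecay)
            p[[nm]] <- r$p; v[[nm]] <- r$v
        }
        return(list(p = p, v = v))
    }
    v <- momentum * v + g + weightDecay * p
    list(p = p - lr * v, v = v)
}
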