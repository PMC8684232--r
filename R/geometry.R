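## Raster geometry: masks, boxes, cropping and pasting.
## Convention everywhere: matrices indexed (row, col); boxes and clicks use
## 0-based pixel coordinates; boxes are half-open.

.assertMask <- function(mask, what = "mask") {
    if (!is.matrix(mask)) stop(what, " must be a matrix")
    if (!all(mask == 0 | mask == 1)) stop(what, " must contain only 0 and 1")
    invisible(TRUE)
}

#' Tight bounding box of a binary mask
#'
#' The smallest half-open box containing every foreground pixel.
#'
#' @param mask binary 0/1 matrix with at least one foreground pixel.
#' @return A \linkS4class{SurroundingBox}.
#' @examples
#' m <- matrix(0, 10, 10); m[6, 8] <- 1
#' tightBbox(m) # box (5,7,6,8) in 0-based half-open coordinates
#' @export
tightBbox <- function(mask) {
    .assertMask(mask)
    idx <- which(mask == 1, arr.ind = TRUE)
    if (nrow(idx) == 0L) stop("mask has no foreground pixels")
    surroundingBox(min(idx[, 1]) - 1L, min(idx[, 2]) - 1L,
                   max(idx[, 1]), max(idx[, 2]))
}

#' Randomly jitter a surrounding box
#'
#' Emulates the looseness of a user-drawn surrounding box: each of the four
#' edges is shifted independently by an integer offset drawn uniformly from
#' \code{[-maxJitter, maxJitter]}, then clamped to the image extent. Draws
#' producing a degenerate box are rejected and resampled, preserving the
#' uniform-offset model. The default of 30 px models typical user looseness.
#'
#' Uses the current R random number generator state; seed with
#' \code{set.seed()} for reproducibility.
#'
#' @param box a \linkS4class{SurroundingBox} valid within \code{extent}.
#' @param maxJitter maximum absolute per-edge offset in pixels (>= 0).
#' @param extent image extent \code{c(H, W)}.
#' @return A jittered \linkS4class{SurroundingBox}.
#' @export
jitterBox <- function(box, maxJitter = 30L, extent) {
    if (maxJitter < 0) stop("maxJitter must be non-negative")
    maxJitter <- as.integer(maxJitter)
    if (maxJitter == 0L) return(box)
    H <- as.integer(extent[1]); W <- as.integer(extent[2])
    repeat {
        off <- sample.int(2L * maxJitter + 1L, 4L, replace = TRUE) - maxJitter - 1L
        top    <- max(0L, min(H - 1L, box@top + off[1]))
        bottom <- max(1L, min(H, box@bottom + off[2]))
        left   <- max(0L, min(W - 1L, box@left + off[3]))
        right  <- max(1L, min(W, box@right + off[4]))
        if (bottom > top && right > left)
            return(surroundingBox(top, left, bottom, right, extent = c(H, W)))
    }
}

#' Crop a raster to a surrounding box
#'
#' @param x matrix or H x W x C array.
#' @param box a \linkS4class{SurroundingBox} inside the extent of \code{x}.
#' @return The \code{[top, bottom) x [left, right)} sub-raster.
#' @export
cropBox <- function(x, box) {
    d <- dim(x)
    if (box@bottom > d[1] || box@right > d[2])
        stop("box lies outside the raster extent")
    rows <- (box@top + 1L):box@bottom
    cols <- (box@left + 1L):box@right
    if (length(d) == 2L) x[rows, cols, drop = FALSE]
    else x[rows, cols, , drop = FALSE]
}

#' Paste a crop back into a full-frame raster
#'
#' Inverse of \code{\link{cropBox}}: writes \code{patch} into the box region
#' of \code{frame} and leaves all other pixels untouched.
#'
#' @param frame full-frame matrix or array.
#' @param patch crop-sized raster matching the box dimensions.
#' @param box the \linkS4class{SurroundingBox} the patch was cropped with.
#' @return The updated frame.
#' @export
pasteBox <- function(frame, patch, box) {
    d <- dim(frame)
    if (box@bottom > d[1] || box@right > d[2])
        stop("box lies outside the raster extent")
    rows <- (box@top + 1L):box@bottom
    cols <- (box@left + 1L):box@right
    pd <- dim(patch)
    if (pd[1] != length(rows) || pd[2] != length(cols))
        stop("patch dimensions do not match the box")
    if (length(d) == 2L) frame[rows, cols] <- patch
    else frame[rows, cols, ] <- patch
    frame
}

#' Threshold a real-valued map into a binary mask
#'
#' A pixel is foreground iff its value strictly exceeds the threshold. The
#' default threshold of 0 matches logit-domain maps, where fusion is defined.
#'
#' @param logits finite numeric matrix.
#' @param threshold decision threshold (default 0).
#' @return Binary 0/1 matrix of the same shape.
#' @export
binarize <- function(logits, threshold = 0) {
    if (!all(is.finite(logits))) stop("logits must be finite")
    out <- (logits > threshold) + 0
    dim(out) <- dim(logits)
    out
}

#' Bilinear resampling of a matrix or multi-channel array
#'
#' Half-pixel-centre aligned bilinear interpolation, used to resize crops to
#' the network input size, guidance maps to feature resolution, and logits
#' back to box resolution.
#'
#' @param x numeric matrix or H x W x C array.
#' @param outDim target \code{c(H, W)}.
#' @return Resampled matrix or array.
#' @export
resizeBilinear <- function(x, outDim) {
    oh <- as.integer(outDim[1]); ow <- as.integer(outDim[2])
    if (is.matrix(x)) return(cpp_resize_bilinear(x, oh, ow))
    d <- dim(x)
    out <- array(0, c(oh, ow, d[3]))
    for (k in seq_len(d[3]))
        out[, , k] <- cpp_resize_bilinear(matrix(x[, , k], d[1], d[2]), oh, ow)
    out
}

## Resize a binary mask: bilinear then re-threshold at 0.5 so the result
## stays crisp 0/1.
.resizeMask <- function(mask, outDim) {
    binarize(resizeBilinear(mask, outDim), 0.5)
}
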