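## Central S4 value classes. Masks and raster maps are plain numeric/integer
## matrices in (row, col) orientation, 0-based pixel indexing in all box and
## click coordinates, boxes half-open: [top, bottom) x [left, right).

#' Surrounding box
#'
#' A loose, user-drawn rectangle that crops the region of interest around a
#' lesion. Coordinates are 0-based pixel indices and the box is half-open:
#' rows \code{[top, bottom)}, columns \code{[left, right)}.
#'
#' @slot top,left,bottom,right integer pixel bounds.
#' @export
setClass("SurroundingBox",
    representation(top = "integer", left = "integer",
                   bottom = "integer", right = "integer"),
    validity = function(object) {
        msg <- character()
        if (length(object@top) != 1L || length(object@left) != 1L ||
            length(object@bottom) != 1L || length(object@right) != 1L)
            msg <- c(msg, "all four bounds must be scalar")
        else {
            if (object@top < 0L || object@left < 0L)
                msg <- c(msg, "top and left must be >= 0")
            if (object@bottom <= object@top)
                msg <- c(msg, "bottom must exceed top")
            if (object@right <= object@left)
                msg <- c(msg, "right must exceed left")
        }
        if (length(msg)) msg else TRUE
    })

#' Create a surrounding box
#'
#' @param top,left,bottom,right pixel bounds, 0-based, half-open.
#' @param extent optional \code{c(H, W)}; when given, the box must fit inside.
#' @return A \linkS4class{SurroundingBox}.
#' @examples
#' surroundingBox(2, 4, 5, 7)
#' @export
surroundingBox <- function(top, left, bottom, right, extent = NULL) {
    box <- new("SurroundingBox", top = as.integer(top), left = as.integer(left),
               bottom = as.integer(bottom), right = as.integer(right))
    if (!is.null(extent)) {
        if (box@bottom > extent[1] || box@right > extent[2])
            stop("box exceeds the image extent")
    }
    box
}

#' Click set
#'
#' Ordered positive and negative user clicks in crop coordinates. A positive
#' click marks a pixel wrongly excluded from the current segmentation; a
#' negative click marks a pixel wrongly included.
#'
#' @slot positives,negatives integer n x 2 matrices of 0-based (row, col)
#'   click positions.
#' @export
setClass("ClickSet",
    representation(positives = "matrix", negatives = "matrix"),
    validity = function(object) {
        msg <- character()
        for (nm in c("positives", "negatives")) {
            m <- slot(object, nm)
            if (ncol(m) != 2L) msg <- c(msg, paste(nm, "must have 2 columns"))
            else if (nrow(m) && any(m < 0)) msg <- c(msg, paste(nm, "must be >= 0"))
        }
        key <- c(paste0("p", apply(object@positives, 1L, paste, collapse = ",")),
                 paste0("n", apply(object@negatives, 1L, paste, collapse = ",")))
        if (anyDuplicated(key))
            msg <- c(msg, "duplicate (row, col, polarity) click")
        if (length(msg)) msg else TRUE
    })

.clickMatrix <- function(x) {
    if (is.null(x) || (is.matrix(x) && nrow(x) == 0L) || length(x) == 0L)
        return(matrix(integer(), 0L, 2L))
    m <- if (is.matrix(x)) x else matrix(x, ncol = 2L, byrow = TRUE)
    storage.mode(m) <- "integer"
    dimnames(m) <- NULL
    m
}

#' Create a click set
#'
#' @param positives,negatives n x 2 matrices (or length-2 vectors, or row-wise
#'   flattened vectors) of 0-based (row, col) positions; may be empty.
#' @return A \linkS4class{ClickSet}.
#' @examples
#' clickSet(positives = rbind(c(3, 4)), negatives = rbind(c(10, 2)))
#' @export
clickSet <- function(positives = NULL, negatives = NULL) {
    new("ClickSet", positives = .clickMatrix(positives),
        negatives = .clickMatrix(negatives))
}

#' Gaussian click guidance channels
#'
#' Two per-pixel maps in [0, 1] encoding proximity to positive (\code{g1})
#' and negative (\code{g2}) clicks; at each pixel the value is the maximum
#' over clicks of \code{exp(-4 d^2 / R^2)} where \code{d} is the Euclidean
#' distance to the click and \code{R} the influence radius.
#'
#' @slot g1,g2 numeric H x W matrices.
#' @slot radius the influence radius R in pixels.
#' @export
setClass("GuidanceMaps",
    representation(g1 = "matrix", g2 = "matrix", radius = "numeric"),
    validity = function(object) {
        msg <- character()
        if (!identical(dim(object@g1), dim(object@g2)))
            msg <- c(msg, "g1 and g2 must share dimensions")
        if (object@radius <= 0) msg <- c(msg, "radius must be positive")
        rng <- range(c(object@g1, object@g2, 0, 1))
        if (rng[1] < 0 || rng[2] > 1)
            msg <- c(msg, "guidance values must lie in [0, 1]")
        if (length(msg)) msg else TRUE
    })

#' Click weight map
#'
#' A polarity-blind per-pixel sum of click Gaussians at a radius much larger
#' than the guidance radius; localizes where the refinement stage is allowed
#' to alter the coarse segmentation.
#'
#' @slot w numeric H x W non-negative matrix.
#' @slot radius the (larger) influence radius in pixels.
#' @export
setClass("WeightMap",
    representation(w = "matrix", radius = "numeric"),
    validity = function(object) {
        msg <- character()
        if (object@radius <= 0) msg <- c(msg, "radius must be positive")
        if (length(object@w) && min(object@w) < 0)
            msg <- c(msg, "weights must be non-negative")
        if (length(msg)) msg else TRUE
    })

#' Coarse / refinement / fused segmentation triple
#'
#' Logit maps of the coarse stage (\code{b}), the click refinement stage
#' (\code{c}) and their fusion \code{f = w * c + b}, together with the weight
#' map \code{w} used for fusion. All maps share the crop resolution.
#'
#' @slot b,c,f,w numeric H x W matrices.
#' @export
setClass("SegmentationTriple",
    representation(b = "matrix", c = "matrix", f = "matrix", w = "matrix"),
    validity = function(object) {
        dims <- list(dim(object@b), dim(object@c), dim(object@f), dim(object@w))
        if (!all(vapply(dims, identical, logical(1), dims[[1]])))
            return("b, c, f, w must share dimensions")
        TRUE
    })

#' Pixel confusion counts
#'
#' @slot tp,tn,fp,fn non-negative pixel counts.
#' @export
setClass("ConfusionCounts",
    representation(tp = "numeric", tn = "numeric", fp = "numeric", fn = "numeric"),
    validity = function(object) {
        v <- c(object@tp, object@tn, object@fp, object@fn)
        if (any(v < 0)) return("counts must be non-negative")
        if (sum(v) <= 0) return("at least one evaluated pixel is required")
        TRUE
    })

#' Segmentation metrics report
#'
#' Accuracy, sensitivity (true positive rate), specificity, Dice coefficient
#' and intersection-over-union computed from pixel confusion counts. A metric
#' whose denominator is zero is undefined and reported as \code{NA}, never
#' silently as 0.
#'
#' @slot acc,sen,spe,dic,iou fractions in [0, 1] or \code{NA} when undefined.
#' @export
setClass("MetricsReport",
    representation(acc = "numeric", sen = "numeric", spe = "numeric",
                   dic = "numeric", iou = "numeric"),
    validity = function(object) {
        v <- c(object@acc, object@sen, object@spe, object@dic, object@iou)
        v <- v[!is.na(v)]
        if (length(v) && (min(v) < -1e-12 || max(v) > 1 + 1e-12))
            return("defined metrics must lie in [0, 1]")
        TRUE
    })

setMethod("show", "SurroundingBox", function(object) {
    cat(sprintf("SurroundingBox [%d,%d) x [%d,%d)  (%d x %d px)\n",
        object@top, object@bottom, object@left, object@right,
        object@bottom - object@top, object@right - object@left))
})

setMethod("show", "ClickSet", function(object) {
    cat(sprintf("ClickSet: %d positive, %d negative click(s)\n",
        nrow(object@positives), nrow(object@negatives)))
})

setMethod("show", "GuidanceMaps", function(object) {
    cat(sprintf("GuidanceMaps %d x %d, radius %.1f px (max g1 %.3f, max g2 %.3f)\n",
        nrow(object@g1), ncol(object@g1), object@radius,
        if (length(object@g1)) max(object@g1) else 0,
        if (length(object@g2)) max(object@g2) else 0))
})

setMethod("show", "MetricsReport", function(object) {
    cat(sprintf("MetricsReport acc=%.4f sen=%.4f spe=%.4f dic=%.4f iou=%.4f\n",
        object@acc, object@sen, object@spe, object@dic, object@iou))
})

#' @describeIn clickSet number of clicks of each polarity
#' @param cs a \linkS4class{ClickSet}
#' @export
nClicks <- function(cs) {
    c(positive = nrow(cs@positives), negative = nrow(cs@negatives))
}

#' Accessors for click positions
#'
#' @param cs a \linkS4class{ClickSet}
#' @return An integer n x 2 matrix of 0-based (row, col) positions.
#' @export
positiveClicks <- function(cs) cs@positives

#' @rdname positiveClicks
#' @export
negativeClicks <- function(cs) cs@negatives

#' Convert a metrics report to a named numeric vector
#'
#' @param m a \linkS4class{MetricsReport}
#' @return Named numeric vector with elements acc, sen, spe, dic, iou.
#' @export
metricsVector <- function(m) {
    c(acc = m@acc, sen = m@sen, spe = m@spe, dic = m@dic, iou = m@iou)
}
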