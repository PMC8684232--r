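## User-interaction simulation: sampling corrective clicks from the two error
## populations of a coarse segmentation (false negatives -> positive clicks,
## false positives -> negative clicks).

#' Sample simulated user clicks from segmentation errors
#'
#' Emulates a user correcting a coarse segmentation: positive clicks are drawn
#' uniformly at random without replacement from the false-negative pixel set
#' (foreground wrongly missed), negative clicks from the false-positive set
#' (background wrongly included). If an error set holds fewer pixels than
#' requested, all of its pixels can be returned but no more. Uses the current
#' RNG state; seed with \code{set.seed()} for reproducibility.
#'
#' @param pred,gt binary 0/1 matrices of identical dimensions.
#' @param nPos,nNeg requested numbers of positive and negative clicks.
#' @return A \linkS4class{ClickSet} in the coordinates of \code{pred}.
#' @export
sampleClicks <- function(pred, gt, nPos, nNeg) {
    if (!identical(dim(pred), dim(gt)))
        stop("pred and gt must have identical dimensions")
    if (nPos < 0 || nNeg < 0) stop("click counts must be non-negative")
    fnIdx <- which(pred == 0 & gt == 1, arr.ind = TRUE)
    fpIdx <- which(pred == 1 & gt == 0, arr.ind = TRUE)
    pick <- function(idx, n) {
        n <- min(n, nrow(idx))
        if (n == 0L) return(matrix(integer(), 0L, 2L))
        sel <- if (nrow(idx) == 1L) 1L else sample.int(nrow(idx), n)
        idx[sel, , drop = FALSE] - 1L
    }
    clickSet(positives = pick(fnIdx, nPos), negatives = pick(fpIdx, nNeg))
}

## Split a total click budget between the two error sets proportionally to
## their sizes (ties resolved toward positive clicks), capped by availability.
.allocateClicks <- function(nTotal, nFN, nFP) {
    if (nTotal <= 0L || (nFN + nFP) == 0L) return(c(pos = 0L, neg = 0L))
    raw <- nTotal * nFN / (nFN + nFP)
    nPos <- as.integer(floor(raw + 0.5))   # round half up -> positive first
    nNeg <- nTotal - nPos
    nPos <- min(nPos, nFN); nNeg <- min(nNeg, nFP)
    # reassign leftover budget to the other set when one is exhausted
    spare <- nTotal - nPos - nNeg
    if (spare > 0L) {
        add <- min(spare, nFN - nPos); nPos <- nPos + add; spare <- spare - add
        nNeg <- nNeg + min(spare, nFP - nNeg)
    }
    c(pos = as.integer(nPos), neg = as.integer(nNeg))
}

#' Sample a fixed click budget split across the two error types
#'
#' Allocates \code{nTotal} clicks to the false-negative and false-positive
#' sets proportionally to their areas (ties toward positive), then samples
#' with \code{\link{sampleClicks}}. This is the sampling strategy used both
#' at training time and in the interactive evaluation protocols.
#'
#' @inheritParams sampleClicks
#' @param nTotal total click budget.
#' @return A \linkS4class{ClickSet}.
#' @export
sampleClickBudget <- function(pred, gt, nTotal) {
    nFN <- sum(pred == 0 & gt == 1)
    nFP <- sum(pred == 1 & gt == 0)
    a <- .allocateClicks(as.integer(nTotal), nFN, nFP)
    sampleClicks(pred, gt, a["pos"], a["neg"])
}

#' Merge two click sets
#'
#' Appends the clicks of \code{extra} to \code{base}, dropping exact
#' duplicates; used by iterative refinement sessions where the click count
#' never decreases.
#'
#' @param base,extra \linkS4class{ClickSet} objects.
#' @return The merged \linkS4class{ClickSet}.
#' @export
mergeClicks <- function(base, extra) {
    dedup <- function(m) m[!duplicated(m), , drop = FALSE]
    clickSet(positives = dedup(rbind(base@positives, extra@positives)),
             negatives = dedup(rbind(base@negatives, extra@negatives)))
}

#' Read and write click sets as JSON
#'
#' Schema: \code{{"positive": [[row, col], ...], "negative": [[row, col], ...]}}
#' in 0-based crop coordinates.
#'
#' @param cs a \linkS4class{ClickSet}.
#' @param path JSON file path.
#' @return \code{writeClicksJson} returns \code{path} invisibly;
#'   \code{readClicksJson} returns a \linkS4class{ClickSet}.
#' @export
writeClicksJson <- function(cs, path) {
    obj <- list(positive = unname(apply(cs@positives, 1L, identity, simplify = FALSE)),
                negative = unname(apply(cs@negatives, 1L, identity, simplify = FALSE)))
    jsonlite::write_json(obj, path, auto_unbox = FALSE)
    invisible(path)
}

#' @rdname writeClicksJson
#' @export
readClicksJson <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    toMat <- function(x) {
        if (is.null(x) || length(x) == 0L) return(NULL)
        if (is.matrix(x)) x else matrix(unlist(x), ncol = 2L, byrow = TRUE)
    }
    clickSet(positives = toMat(obj$positive), negatives = toMat(obj$negative))
}

#' Read and write surrounding boxes as JSON
#'
#' Schema: \code{{"top": int, "left": int, "bottom": int, "right": int}},
#' 0-based half-open.
#'
#' @param box a \linkS4class{SurroundingBox}.
#' @param path JSON file path.
#' @export
writeBoxJson <- function(box, path) {
    jsonlite::write_json(list(top = box@top, left = box@left,
                              bottom = box@bottom, right = box@right),
                         path, auto_unbox = TRUE)
    invisible(path)
}

#' @rdname writeBoxJson
#' @export
readBoxJson <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    surroundingBox(obj$top, obj$left, obj$bottom, obj$right)
}
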