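## Gaussian click encodings and residual fusion.
##
## Guidance channels: per pixel (m, n) the maximum over clicks s_{i,j} of
##   exp(-4 * ((m-i)^2 + (n-j)^2) / R^2),
## one channel per click polarity. Weight map: the same kernel at a much
## larger radius, summed (not maximized) over all clicks regardless of
## polarity. Fusion: F = W * C + B elementwise in the logit domain, so the
## refinement is an additive correction confined to clicked neighbourhoods.

#' Gaussian distance map of a set of clicks
#'
#' @param clicks integer n x 2 matrix of 0-based (row, col) positions (may be
#'   empty).
#' @param radius influence radius R in pixels (> 0).
#' @param shape output \code{c(H, W)}.
#' @param mode \code{"max"} (guidance channels) or \code{"sum"} (weight map).
#' @return H x W numeric matrix; all-zero when no clicks.
#' @export
gaussianGuidance <- function(clicks, radius, shape, mode = c("max", "sum")) {
    mode <- match.arg(mode)
    if (radius <= 0) stop("radius must be positive")
    m <- .clickMatrix(clicks)
    if (nrow(m) && (max(m[, 1]) >= shape[1] || max(m[, 2]) >= shape[2]))
        stop("clicks must lie inside the map")
    cpp_click_kernel(matrix(as.numeric(m), ncol = 2L),
                     as.integer(shape[1]), as.integer(shape[2]),
                     radius, if (mode == "max") 0L else 1L)
}

#' Encode a click set as two Gaussian guidance channels
#'
#' @param cs a \linkS4class{ClickSet} in crop coordinates.
#' @param radius influence radius R in pixels.
#' @param shape crop \code{c(H, W)}.
#' @return A \linkS4class{GuidanceMaps}: g1 from positive clicks, g2 from
#'   negative clicks.
#' @export
encodeClicks <- function(cs, radius, shape) {
    new("GuidanceMaps",
        g1 = gaussianGuidance(cs@positives, radius, shape, "max"),
        g2 = gaussianGuidance(cs@negatives, radius, shape, "max"),
        radius = radius)
}

#' Polarity-blind click weight map
#'
#' Sums (never clamps) the Gaussian kernels of all clicks of either polarity
#' at radius \code{radius}, which should be much larger than the guidance
#' radius so each click licenses correction over a broad neighbourhood.
#'
#' @param cs a \linkS4class{ClickSet}.
#' @param radius weight-map radius in pixels.
#' @param shape crop \code{c(H, W)}.
#' @return A \linkS4class{WeightMap}.
#' @export
weightMap <- function(cs, radius, shape) {
    allClicks <- rbind(cs@positives, cs@negatives)
    new("WeightMap",
        w = gaussianGuidance(allClicks, radius, shape, "sum"),
        radius = radius)
}

#' Residual fusion of coarse and refinement logits
#'
#' \code{f = w * c + b} elementwise: where no clicks were placed (w = 0) the
#' fused result is bit-identical to the coarse result; near clicks the
#' refinement logits override or correct it.
#'
#' @param b coarse-stage logit matrix.
#' @param c refinement-stage logit matrix.
#' @param w weight matrix or \linkS4class{WeightMap}.
#' @return Fused logit matrix.
#' @export
fuseLogits <- function(b, c, w) {
    if (is(w, "WeightMap")) w <- w@w
    if (!identical(dim(b), dim(c)) || !identical(dim(b), dim(w)))
        stop("b, c and w must share dimensions")
    w * c + b
}
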