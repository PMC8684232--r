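## Independent brute-force oracles used to check the vectorized / compiled
## implementations. These stay deliberately naive (explicit double loops).

oracleConfusion <- function(pred, gt) {
    tp <- tn <- fp <- fn <- 0L
    for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
        p <- pred[i, j]; g <- gt[i, j]
        if (p == 1 && g == 1) tp <- tp + 1L
        else if (p == 1 && g == 0) fp <- fp + 1L
        else if (p == 0 && g == 1) fn <- fn + 1L
        else tn <- tn + 1L
    }
    c(tp = tp, tn = tn, fp = fp, fn = fn)
}

## Gaussian click map by explicit loops over pixels and clicks.
## clicks: n x 2 matrix of 0-based (row, col); mode "max" or "sum".
oracleClickMap <- function(clicks, radius, shape, mode = "max") {
    out <- matrix(0, shape[1], shape[2])
    if (is.null(clicks) || nrow(clicks) == 0L) return(out)
    for (m in seq_len(shape[1])) for (n in seq_len(shape[2])) {
        vals <- numeric(nrow(clicks))
        for (k in seq_len(nrow(clicks))) {
            d2 <- (m - 1 - clicks[k, 1])^2 + (n - 1 - clicks[k, 2])^2
            vals[k] <- exp(-4 * d2 / radius^2)
        }
        out[m, n] <- if (mode == "max") max(vals) else sum(vals)
    }
    out
}

randomMask <- function(h, w, p = 0.4) (matrix(runif(h * w), h, w) < p) + 0

randomClicks <- function(n, shape) {
    if (n == 0L) return(matrix(integer(), 0L, 2L))
    # distinct pixels, so click sets built from the result are valid
    cells <- sample.int(shape[1] * shape[2], n) - 1L
    cbind(cells %% shape[1], cells %/% shape[1])
}
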