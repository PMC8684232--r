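test_that("confusion counts match hand-checked and brute-force cases", {
    pred <- matrix(0, 10, 10); pred[1:3, 1:3] <- 1
    gt <- matrix(0, 10, 10); gt[1:3, 2:4] <- 1
    cc <- confusionCounts(pred, gt)
    expect_equal(c(cc@tp, cc@fp, cc@fn, cc@tn), c(6, 3, 3, 88))

    # identity and complement cases
    m <- randomMask(8, 8)
    cc <- confusionCounts(m, m)
    expect_equal(cc@tp, sum(m)); expect_equal(cc@tn, 64 - sum(m))
    expect_equal(cc@fp + cc@fn, 0)
    cc <- confusionCounts(1 - m, m)
    expect_equal(cc@tp + cc@tn, 0)
    expect_equal(c(cc@fp, cc@fn), c(sum(1 - m), sum(m)))

    expect_error(confusionCounts(matrix(0, 3, 3), matrix(0, 4, 4)),
                 "identical dimensions")

    set.seed(71)
    for (r in 1:25) {
        h <- sample(2:32, 1); w <- sample(2:32, 1)
        pred <- randomMask(h, w); gt <- randomMask(h, w)
        cc <- confusionCounts(pred, gt)
        o <- oracleConfusion(pred, gt)
        expect_identical(c(cc@tp, cc@tn, cc@fp, cc@fn), unname(as.numeric(o)))
        expect_equal(cc@tp + cc@tn + cc@fp + cc@fn, h * w)
    }
})

test_that("metrics implement the confusion-ratio formulas with NA for 0/0", {
    m <- computeMetrics(new("ConfusionCounts", tp = 6, fp = 3, fn = 3, tn = 88))
    expect_equal(m@acc, 0.94)
    expect_equal(m@sen, 2 / 3, tolerance = 1e-12)
    expect_equal(m@spe, 88 / 91, tolerance = 1e-12)
    expect_equal(m@dic, 2 / 3, tolerance = 1e-12)
    expect_equal(m@iou, 0.5)

    perfect <- computeMetrics(new("ConfusionCounts", tp = 5, fp = 0, fn = 0, tn = 9))
    expect_equal(unname(metricsVector(perfect)), rep(1, 5))

    emptyPred <- computeMetrics(new("ConfusionCounts", tp = 0, fp = 0, fn = 5, tn = 95))
    expect_equal(metricsVector(emptyPred),
                 c(acc = 0.95, sen = 0, spe = 1, dic = 0, iou = 0))

    # zero denominators are undefined, never 0
    noFg <- computeMetrics(new("ConfusionCounts", tp = 0, fp = 0, fn = 0, tn = 10))
    expect_true(is.na(noFg@sen) && is.na(noFg@dic) && is.na(noFg@iou))
    expect_equal(noFg@acc, 1)
    expect_error(computeMetrics(new("ConfusionCounts", tp = 0, fp = 0,
                                    fn = 0, tn = 0)))
})

test_that("metric identities hold on random mask pairs", {
    set.seed(72)
    for (r in 1:40) {
        h <- sample(2:32, 1); w <- sample(2:32, 1)
        pred <- randomMask(h, w); gt <- randomMask(h, w)
        m <- maskMetrics(pred, gt)
        v <- metricsVector(m)
        defined <- v[!is.na(v)]
        expect_true(all(defined >= 0 & defined <= 1))
        if (!is.na(m@iou)) {
            expect_equal(m@dic, 2 * m@iou / (1 + m@iou), tolerance = 1e-12)
            expect_equal(m@dic == 1, identical(pred, gt) && sum(gt) > 0)
        }
        # complement symmetry: TP<->TN, FP<->FN
        a <- confusionCounts(pred, gt); b <- confusionCounts(1 - pred, 1 - gt)
        expect_equal(c(a@tp, a@fp), c(b@tn, b@fn))
    }
})

test_that("binarize is a strict threshold and shift-invariant", {
    expect_equal(binarize(matrix(0, 4, 4)), matrix(0, 4, 4))
    expect_equal(binarize(matrix(c(-1, 1), 1, 2)), matrix(c(0, 1), 1, 2))
    expect_error(binarize(matrix(c(0, NaN), 1, 2)), "finite")
    set.seed(73)
    for (r in 1:10) {
        x <- matrix(rnorm(64), 8, 8)
        t <- rnorm(1)
        expect_identical(binarize(x, t), binarize(x - t, 0))
    }
})

test_that("tight bounding boxes and crop/paste round-trips are exact", {
    m <- matrix(0, 10, 10); m[6, 8] <- 1
    b <- tightBbox(m)
    expect_equal(c(b@top, b@left, b@bottom, b@right), c(5, 7, 6, 8))

    full <- matrix(1, 7, 9)
    b <- tightBbox(full)
    expect_equal(c(b@top, b@left, b@bottom, b@right), c(0, 0, 7, 9))

    m <- matrix(0, 10, 10); m[3:5, 5:7] <- 1   # corners (2,4)..(4,6) 0-based
    b <- tightBbox(m)
    expect_equal(c(b@top, b@left, b@bottom, b@right), c(2, 4, 5, 7))
    expect_error(tightBbox(matrix(0, 4, 4)), "foreground")

    # crop shape, identity, and bit-exact paste-back
    x <- matrix(rnorm(100), 10, 10)
    expect_equal(dim(cropBox(x, b)), c(3, 3))
    expect_identical(cropBox(x, surroundingBox(0, 0, 10, 10)), x)
    patch <- cropBox(x, b)
    expect_identical(pasteBox(x, patch, b), x)
    expect_error(cropBox(x, surroundingBox(5, 5, 11, 8)), "outside")

    # tight box of the crop of the tight box spans the whole crop
    set.seed(74)
    for (r in 1:10) {
        m <- randomMask(12, 15, 0.2)
        if (sum(m) == 0) next
        b <- tightBbox(m)
        cr <- cropBox(m, b)
        b2 <- tightBbox(cr)
        expect_equal(c(b2@top, b2@left, b2@bottom, b2@right),
                     c(0, 0, nrow(cr), ncol(cr)))
    }
})

test_that("metrics CSV writes one row per sample with empty undefined cells", {
    reps <- list(a = computeMetrics(new("ConfusionCounts", tp = 6, fp = 3,
                                        fn = 3, tn = 88)),
                 b = computeMetrics(new("ConfusionCounts", tp = 0, fp = 0,
                                        fn = 0, tn = 10)))
    f <- tempfile(fileext = ".csv")
    writeMetricsCsv(reps, f)
    df <- read.csv(f)
    expect_equal(nrow(df), 2)
    expect_equal(df$sample_id, c("a", "b"))
    expect_true(is.na(df$iou[2]))
    expect_equal(df$iou[1], 0.5)
})
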