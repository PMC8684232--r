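test_that("box jitter respects its contract and is seed-reproducible", {
    ext <- c(600, 600)
    box <- surroundingBox(200, 200, 400, 400)
    expect_identical(jitterBox(box, 0L, ext), box)
    expect_error(jitterBox(box, -1, ext), "non-negative")

    set.seed(81)
    for (r in 1:200) {
        jb <- jitterBox(box, 30L, ext)
        expect_true(abs(jb@top - box@top) <= 30 && abs(jb@bottom - box@bottom) <= 30)
        expect_true(abs(jb@left - box@left) <= 30 && abs(jb@right - box@right) <= 30)
        expect_true(jb@bottom > jb@top && jb@right > jb@left)
        expect_true(jb@top >= 0 && jb@left >= 0 &&
                    jb@bottom <= 600 && jb@right <= 600)
    }

    set.seed(99); a <- jitterBox(box, 30L, ext)
    set.seed(99); b <- jitterBox(box, 30L, ext)
    expect_identical(a, b)

    # clamping keeps tiny boxes near the border valid
    set.seed(82)
    edge <- surroundingBox(0, 0, 3, 3)
    for (r in 1:50) {
        jb <- jitterBox(edge, 30L, c(10, 10))
        expect_true(jb@bottom > jb@top && jb@right > jb@left)
        expect_true(jb@bottom <= 10 && jb@right <= 10)
    }
})

test_that("sampled clicks land only on segmentation mistakes", {
    gt <- matrix(0, 12, 12); gt[4:9, 4:9] <- 1

    # no mistakes -> no clicks
    set.seed(83)
    cs <- sampleClicks(gt, gt, 5L, 5L)
    expect_equal(sum(nClicks(cs)), 0)

    # all-zero prediction: FN set is the whole foreground
    cs <- sampleClicks(matrix(0, 12, 12), gt, 3L, 4L)
    expect_equal(unname(nClicks(cs)), c(3, 0))
    pos <- positiveClicks(cs)
    expect_true(all(gt[cbind(pos[, 1] + 1, pos[, 2] + 1)] == 1))

    # polarity consistency over many draws on a mixed-error prediction
    pred <- matrix(0, 12, 12); pred[2:7, 2:7] <- 1
    set.seed(84)
    for (r in 1:100) {
        cs <- sampleClicks(pred, gt, 2L, 2L)
        p <- positiveClicks(cs); n <- negativeClicks(cs)
        expect_true(all(pred[cbind(p[, 1] + 1, p[, 2] + 1)] == 0 &
                        gt[cbind(p[, 1] + 1, p[, 2] + 1)] == 1))
        expect_true(all(pred[cbind(n[, 1] + 1, n[, 2] + 1)] == 1 &
                        gt[cbind(n[, 1] + 1, n[, 2] + 1)] == 0))
    }

    # requesting more clicks than available returns all available, no dupes
    cs <- sampleClicks(matrix(0, 12, 12), gt, 100L, 100L)
    expect_equal(unname(nClicks(cs)), c(36, 0))
    expect_false(anyDuplicated(positiveClicks(cs)) > 0)
})

test_that("click sampling is uniform over the error set", {
    gt <- matrix(0, 10, 10); gt[3:7, 3:7] <- 1   # 25 FN pixels
    pred <- matrix(0, 10, 10)
    nDraw <- 1000L
    counts <- matrix(0, 10, 10)
    set.seed(85)
    for (r in seq_len(nDraw)) {
        p <- positiveClicks(sampleClicks(pred, gt, 1L, 0L))
        counts[p[1, 1] + 1, p[1, 2] + 1] <- counts[p[1, 1] + 1, p[1, 2] + 1] + 1
    }
    expect_equal(sum(counts), nDraw)
    expect_true(all(counts[gt == 0] == 0))
    # per-pixel frequency within 4 sigma of the binomial expectation
    expected <- nDraw / 25
    sigma <- sqrt(nDraw * (1 / 25) * (24 / 25))
    expect_true(all(abs(counts[gt == 1] - expected) <= 4 * sigma))
})

test_that("click budgets split proportionally with ties toward positive", {
    expect_equal(unname(ClickSeg:::.allocateClicks(3L, 10L, 10L)), c(2L, 1L))
    expect_equal(unname(ClickSeg:::.allocateClicks(2L, 30L, 10L)), c(2L, 0L))
    expect_equal(unname(ClickSeg:::.allocateClicks(2L, 0L, 0L)), c(0L, 0L))
    # a tiny error set gets rounded out of the budget entirely
    expect_equal(unname(ClickSeg:::.allocateClicks(4L, 1L, 50L)), c(0L, 4L))
    # allocation is capped by availability
    expect_equal(unname(ClickSeg:::.allocateClicks(4L, 3L, 1L)), c(3L, 1L))
    expect_equal(unname(ClickSeg:::.allocateClicks(6L, 2L, 2L)), c(2L, 2L))
    expect_equal(unname(ClickSeg:::.allocateClicks(5L, 3L, 0L)), c(3L, 0L))
    gt <- matrix(0, 8, 8); gt[2:5, 2:5] <- 1
    set.seed(86)
    cs <- sampleClickBudget(matrix(0, 8, 8), gt, 2L)
    expect_equal(unname(nClicks(cs)), c(2, 0))
})

test_that("clicks and boxes round-trip through their JSON schemas", {
    cs <- clickSet(positives = rbind(c(3L, 4L), c(7L, 1L)),
                   negatives = rbind(c(0L, 9L)))
    f <- tempfile(fileext = ".json")
    writeClicksJson(cs, f)
    back <- readClicksJson(f)
    expect_identical(positiveClicks(back), positiveClicks(cs))
    expect_identical(negativeClicks(back), negativeClicks(cs))

    empty <- readClicksJson(writeClicksJson(clickSet(), tempfile()))
    expect_equal(sum(nClicks(empty)), 0)

    box <- surroundingBox(2, 4, 10, 12)
    f2 <- tempfile(fileext = ".json")
    writeBoxJson(box, f2)
    expect_identical(readBoxJson(f2), box)
    obj <- jsonlite::read_json(f2)
    expect_named(obj, c("top", "left", "bottom", "right"))
})

test_that("duplicate clicks are rejected and merging deduplicates", {
    expect_error(clickSet(positives = rbind(c(1L, 1L), c(1L, 1L))), "duplicate")
    a <- clickSet(positives = rbind(c(1L, 1L)))
    b <- clickSet(positives = rbind(c(1L, 1L), c(2L, 2L)),
                  negatives = rbind(c(1L, 1L)))   # same pixel, other polarity: fine
    m <- mergeClicks(a, b)
    expect_equal(unname(nClicks(m)), c(2, 1))
})
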