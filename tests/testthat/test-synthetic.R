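test_that("a harmonic-free, noise-free specification yields an exact disk", {
    spec <- lesionSpec(imageSize = 64L, radiusRange = c(12, 12), nHarmonics = 0L,
                       harmonicAmp = 0, lesionContrast = 70, noiseSd = 0,
                       artifactProb = 0, blurSigma = 0, seed = 21L)
    s <- generateSample(spec)
    expect_equal(dim(s$image), c(64, 64, 3))

    # the mask is the rasterized disk: compare to a brute-force rasterization
    idx <- which(s$mask == 1, arr.ind = TRUE)
    ctr <- colMeans(idx)
    disk <- matrix(0, 64, 64)
    for (i in 1:64) for (j in 1:64)
        disk[i, j] <- (sqrt((i - ctr[1])^2 + (j - ctr[2])^2) < 12) + 0
    expect_lt(sum(abs(disk - s$mask)), 2 * pi * 12)  # rasterization band
    expect_lt(abs(sum(s$mask) - pi * 12^2), 2 * pi * 12)

    # the lesion is darker than the background in every channel
    inside <- mean(s$image[, , 1][s$mask == 1])
    outside <- mean(s$image[, , 1][s$mask == 0])
    expect_lt(inside, outside - 10)
})

test_that("generation is bit-identical under the same seed", {
    spec <- lesionSpec(imageSize = 48L, seed = 77L)
    a <- generateSample(spec)
    b <- generateSample(spec)
    expect_identical(a, b)
    spec2 <- spec; spec2@seed <- 78L
    expect_false(identical(generateSample(spec2), a))
})

test_that("masks are single connected components without holes", {
    for (sd_ in c(31L, 32L, 33L, 34L, 35L)) {
        s <- generateSample(lesionSpec(imageSize = 64L, artifactProb = 0,
                                       seed = sd_))
        lab <- EBImage::bwlabel(s$mask)
        expect_equal(max(lab), 1)
        # background of the complement is one component -> no holes
        bg <- EBImage::bwlabel(1 - s$mask)
        expect_equal(max(bg), 1)
    }
})

test_that("masks are non-empty, interior, and artifacts never overlap them", {
    nWithArtifact <- 0L
    for (r in 1:12) {
        # blur/noise disabled so artifact pixels are exactly the image diff
        spec <- lesionSpec(imageSize = 64L, artifactProb = 1, noiseSd = 0,
                           blurSigma = 0, seed = 4000L + r)
        s <- generateSample(spec)
        expect_gt(sum(s$mask), 0)
        # strictly inside the frame: the tight box never touches the border
        b <- tightBbox(s$mask)
        expect_true(b@top > 0 && b@left > 0 && b@bottom < 64 && b@right < 64)

        # the distractor darkens pixels, none of them inside the mask
        spec0 <- spec; spec0@artifactProb <- 0
        s0 <- generateSample(spec0)
        expect_identical(s$mask, s0$mask)
        artifactPx <- (abs(s$image[, , 1] - s0$image[, , 1]) > 1e-9) + 0
        expect_equal(sum(artifactPx * s$mask), 0)
        if (sum(artifactPx) > 0) nWithArtifact <- nWithArtifact + 1L
    }
    expect_gt(nWithArtifact, 6)
})

test_that("more distractors never make coarse segmentation easier", {
    fx <- microFixture()
    easy <- generateSamples(lesionSpec(imageSize = 64L, artifactProb = 0),
                            100, seed = 8000)
    hard <- generateSamples(lesionSpec(imageSize = 64L, artifactProb = 1),
                            100, seed = 8000)
    iouEasy <- evaluateDataset(fx$sboxModel, easy, nClicks = 0L,
                               seed = 1L)$means["base_iou"]
    iouHard <- evaluateDataset(fx$sboxModel, hard, nClicks = 0L,
                               seed = 1L)$means["base_iou"]
    expect_gte(unname(iouEasy), unname(iouHard))
})

test_that("dataset files round-trip through PNG with a complete manifest", {
    out <- file.path(tempdir(), "clickseg-ds-test")
    unlink(out, recursive = TRUE)
    spec <- lesionSpec(imageSize = 48L)
    man <- generateDataset(spec, 1L, seed = 90L, outDir = out)
    expect_equal(nrow(man), 1)
    expect_true(file.exists(file.path(out, "manifest.csv")))
    pngs <- list.files(out, pattern = "\\.png$")
    expect_length(pngs, 2)

    img <- readImagePng(file.path(out, man$image[1]))
    msk <- readMaskPng(file.path(out, man$mask[1]))
    mem <- generateSamples(spec, 1L, seed = 90L)[[1]]
    expect_identical(msk, mem$mask)
    expect_true(max(abs(img - round(mem$image))) <= 1)  # 8-bit quantization

    # regeneration with the same seed gives identical file hashes
    out2 <- file.path(tempdir(), "clickseg-ds-test2")
    unlink(out2, recursive = TRUE)
    generateDataset(spec, 1L, seed = 90L, outDir = out2)
    h1 <- tools::md5sum(file.path(out, sort(pngs)))
    h2 <- tools::md5sum(file.path(out2, sort(pngs)))
    expect_identical(unname(h1), unname(h2))
    unlink(out, recursive = TRUE); unlink(out2, recursive = TRUE)
})
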