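## Synthetic dermoscopy-like image generator. Each sample is a skin-toned
## background with smooth shading and sensor-like noise, one darker
## star-convex lesion blob with an irregular (radial-harmonic) boundary, and
## optional distractor artifacts (dark blots, hair-like streaks) placed
## strictly outside the lesion, so an intensity-driven segmenter makes exactly
## the false-positive mistakes the click-refinement stage exists to fix. The
## ground-truth mask is the exact analytic blob interior, defined before any
## blurring, so masks are crisp while image boundaries are soft.

#' Synthetic lesion specification
#'
#' @slot imageSize square image side in pixels.
#' @slot radiusRange lesion base-radius interval in pixels.
#' @slot nHarmonics number of radial boundary-perturbation harmonics.
#' @slot harmonicAmp total relative amplitude of the boundary perturbation.
#' @slot lesionContrast how much darker the lesion is (8-bit intensity units).
#' @slot noiseSd Gaussian pixel-noise standard deviation (intensity units).
#' @slot artifactProb probability a distractor artifact is added.
#' @slot blurSigma boundary blur in pixels.
#' @slot seed generation seed.
#' @export
setClass("LesionSpec",
    representation(imageSize = "integer", radiusRange = "numeric",
                   nHarmonics = "integer", harmonicAmp = "numeric",
                   lesionContrast = "numeric", noiseSd = "numeric",
                   artifactProb = "numeric", blurSigma = "numeric",
                   seed = "integer"),
    validity = function(object) {
        msg <- character()
        if (any(object@radiusRange <= 0) ||
            max(object@radiusRange) * (1 + object@harmonicAmp) >=
                object@imageSize / 2)
            msg <- c(msg, "radius range must be positive and fit the image")
        if (object@artifactProb < 0 || object@artifactProb > 1)
            msg <- c(msg, "artifactProb must lie in [0, 1]")
        if (length(msg)) msg else TRUE
    })

#' Create a synthetic lesion specification
#'
#' Defaults emulate a 96 px dermoscopy-like scene: lesion radius between 1/6
#' and 1/3 of the image side, four boundary harmonics (the k-th perturbing the
#' radius by up to \code{harmonicAmp / k}), a lesion darker than skin by a
#' per-image contrast drawn between 45% and 100% of \code{lesionContrast}
#' (dermoscopic lesions range from faint to near-black), noise standard
#' deviation 8, boundary blur 2 px and a distractor artifact on half of the
#' images. Distractor blots share the lesion's intensity and sit adjacent to
#' it, so they enter the cropped region of interest and fool intensity-driven
#' segmentation -- the mistake class click refinement exists to fix.
#'
#' @param imageSize image side in pixels.
#' @param radiusRange lesion base-radius interval in pixels; default scales
#'   with \code{imageSize}.
#' @param nHarmonics,harmonicAmp boundary-irregularity controls.
#' @param lesionContrast,noiseSd,blurSigma intensity controls.
#' @param artifactProb distractor-artifact probability.
#' @param seed generation seed.
#' @return A \linkS4class{LesionSpec}.
#' @export
lesionSpec <- function(imageSize = 96L, radiusRange = NULL, nHarmonics = 4L,
                       harmonicAmp = 0.25, lesionContrast = 70, noiseSd = 8,
                       artifactProb = 0.5, blurSigma = 2, seed = 1L) {
    if (is.null(radiusRange)) radiusRange <- imageSize * c(1 / 6, 1 / 3)
    new("LesionSpec", imageSize = as.integer(imageSize),
        radiusRange = radiusRange, nHarmonics = as.integer(nHarmonics),
        harmonicAmp = harmonicAmp, lesionContrast = lesionContrast,
        noiseSd = noiseSd, artifactProb = artifactProb,
        blurSigma = blurSigma, seed = as.integer(seed))
}

## Analytic star-convex interior test: pixel (r, c) is inside iff its distance
## to the centre is below r(theta) = r0 * (1 + sum_k a_k sin(k theta + phi_k)).
.blobMask <- function(n, centre, r0, amps, phases) {
    rows <- matrix(seq_len(n) - 1, n, n)
    cols <- t(rows)
    dr <- rows - centre[1]; dc <- cols - centre[2]
    dist <- sqrt(dr^2 + dc^2)
    theta <- atan2(dc, dr)
    perturb <- 0
    for (k in seq_along(amps))
        perturb <- perturb + amps[k] * sin(k * theta + phases[k])
    (dist < r0 * (1 + perturb)) + 0
}

.drawBlot <- function(n, mask, centre, rmax) {
    # a lesion-toned disk strictly outside the mask but adjacent to it, so it
    # lands inside the cropped region of interest
    rows <- matrix(seq_len(n) - 1, n, n); cols <- t(rows)
    for (attempt in 1:50) {
        r <- runif(1, n / 16, n / 8)
        ang <- runif(1, 0, 2 * pi)
        d <- rmax + r + runif(1, 1, n / 10)
        ctr <- centre + d * c(cos(ang), sin(ang))
        if (any(ctr < r + 1) || any(ctr > n - r - 1)) next
        blot <- (sqrt((rows - ctr[1])^2 + (cols - ctr[2])^2) < r) + 0
        if (sum(blot * mask) == 0) return(blot)
    }
    matrix(0, n, n)
}

.drawStreak <- function(n, mask) {
    # a hair-like dark polyline (quadratic Bezier across the frame), clipped
    # to stay out of the lesion
    p0 <- runif(2, 0, n - 1)
    p1 <- runif(2, 0, n - 1)
    pm <- runif(2, 0, n - 1)
    t <- seq(0, 1, length.out = 4L * n)
    px <- (1 - t)^2 * p0[1] + 2 * t * (1 - t) * pm[1] + t^2 * p1[1]
    py <- (1 - t)^2 * p0[2] + 2 * t * (1 - t) * pm[2] + t^2 * p1[2]
    streak <- matrix(0, n, n)
    ij <- cbind(pmin(pmax(round(px), 0), n - 1), pmin(pmax(round(py), 0), n - 1)) + 1
    streak[ij] <- 1
    # two pixels wide so the streak survives downsampling
    streak[pmin(ij[, 1] + 1L, n) + (ij[, 2] - 1L) * n] <- 1
    streak * (1 - mask)
}

#' Generate one synthetic dermoscopy-like sample
#'
#' Deterministic given \code{spec@seed}: the same specification always yields
#' a bit-identical image and mask.
#'
#' @param spec a \linkS4class{LesionSpec}.
#' @return List with \code{image} (H x W x 3 array, values 0-255) and
#'   \code{mask} (binary matrix, the exact pre-blur blob interior).
#' @export
generateSample <- function(spec) {
    set.seed(spec@seed)
    n <- spec@imageSize
    ## skin-toned background with a smooth random linear shading gradient
    base <- c(205, 160, 140) + runif(3, -15, 15)
    dirv <- runif(2, -1, 1)
    rows <- matrix(seq_len(n) - 1, n, n); cols <- t(rows)
    ramp <- (dirv[1] * rows + dirv[2] * cols) / n
    ramp <- ramp - mean(ramp)
    shade <- 20 * ramp
    ## lesion geometry: resample until the perturbed blob fits the frame
    maxHalf <- (n - 1) / 2 - 1
    if (spec@radiusRange[1] + 2 >= maxHalf)
        stop("radius range too large for the image size")
    repeat {
        r0 <- runif(1, spec@radiusRange[1], spec@radiusRange[2])
        amps <- if (spec@nHarmonics > 0L)
            runif(spec@nHarmonics, 0,
                  spec@harmonicAmp / seq_len(spec@nHarmonics))
        else numeric(0)
        phases <- if (spec@nHarmonics > 0L)
            runif(spec@nHarmonics, 0, 2 * pi)
        else numeric(0)
        margin <- r0 * (1 + sum(amps)) + 2
        if (margin < maxHalf) break
    }
    centre <- runif(2, margin, n - 1 - margin)
    mask <- .blobMask(n, centre, r0, amps, phases)
    ## lesion fill: darker, slightly reddish-brown shifted per channel, with a
    ## per-image contrast scale (lesions range from faint to near-black)
    cscale <- runif(1, 0.45, 1)
    contrast <- spec@lesionContrast * cscale * c(1, 1.15, 1.05) + runif(3, -5, 5)
    img <- array(0, c(n, n, 3))
    for (k in 1:3) img[, , k] <- base[k] + shade - mask * contrast[k]
    ## distractor artifact strictly outside the mask
    if (runif(1) < spec@artifactProb) {
        art <- if (runif(1) < 0.5) .drawBlot(n, mask, centre, margin)
               else .drawStreak(n, mask)
        for (k in 1:3) img[, , k] <- img[, , k] - art * contrast[k]
    }
    ## soft boundaries, then sensor-like noise
    if (spec@blurSigma > 0)
        for (k in 1:3) img[, , k] <- EBImage::gblur(img[, , k], spec@blurSigma)
    if (spec@noiseSd > 0)
        img <- img + array(rnorm(length(img), 0, spec@noiseSd), dim(img))
    img <- pmin(pmax(img, 0), 255)
    list(image = img, mask = mask)
}

#' Generate a dataset of synthetic samples on disk
#'
#' Writes \code{n} PNG image/mask pairs (8-bit RGB images; single-channel
#' masks with 0 = background, 255 = lesion) plus a manifest CSV with columns
#' id, image, mask, spec_hash. Sample \code{i} uses seed \code{seed + i - 1},
#' so regeneration with the same seed is bit-identical.
#'
#' @param spec a \linkS4class{LesionSpec} (its own seed slot is ignored).
#' @param n number of samples (>= 1).
#' @param seed base seed.
#' @param outDir output directory (created if missing).
#' @return The manifest data.frame, invisibly written to
#'   \code{file.path(outDir, "manifest.csv")}.
#' @export
generateDataset <- function(spec, n, seed, outDir) {
    if (n < 1L) stop("n must be >= 1")
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(outDir)) stop("cannot create output directory")
    hash <- .specHash(spec)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
        s <- generateSample(.respecSeed(spec, seed + i - 1L))
        id <- sprintf("sample_%04d", i)
        imgPath <- file.path(outDir, paste0(id, "_image.png"))
        mskPath <- file.path(outDir, paste0(id, "_mask.png"))
        writeImagePng(s$image, imgPath)
        writeMaskPng(s$mask, mskPath)
        rows[[i]] <- data.frame(id = id, image = basename(imgPath),
                                mask = basename(mskPath), spec_hash = hash)
    }
    manifest <- do.call(rbind, rows)
    write.csv(manifest, file.path(outDir, "manifest.csv"), row.names = FALSE)
    invisible(manifest)
}

#' Generate a dataset of synthetic samples in memory
#'
#' As \code{\link{generateDataset}} but returning the list of samples directly
#' (the form the training functions consume).
#'
#' @inheritParams generateDataset
#' @return List of \code{n} samples, each with \code{image} and \code{mask}.
#' @export
generateSamples <- function(spec, n, seed) {
    lapply(seq_len(n), function(i)
        generateSample(.respecSeed(spec, seed + i - 1L)))
}

.respecSeed <- function(spec, seed) {
    spec@seed <- as.integer(seed %% .Machine$integer.max)
    spec
}

.specHash <- function(spec) {
    txt <- paste(spec@imageSize, paste(spec@radiusRange, collapse = ","),
                 spec@nHarmonics, spec@harmonicAmp, spec@lesionContrast,
                 spec@noiseSd, spec@artifactProb, spec@blurSigma, sep = "|")
    f <- tempfile()
    writeLines(txt, f)
    unname(tools::md5sum(f))
}

## ---- PNG I/O ---------------------------------------------------------------

#' Read and write binary masks and RGB images as PNG
#'
#' Masks are single-channel 8-bit PNGs with 0 = background and 255 = lesion;
#' reading maps 255 to 1. Images are 8-bit RGB.
#'
#' @param mask binary 0/1 matrix.
#' @param image H x W x 3 array with values 0-255.
#' @param path PNG file path.
#' @export
writeMaskPng <- function(mask, path) {
    .assertMask(mask)
    png::writePNG(mask, path)
    invisible(path)
}

#' @rdname writeMaskPng
#' @export
readMaskPng <- function(path) {
    m <- png::readPNG(path)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    (m > 0.5) + 0
}

#' @rdname writeMaskPng
#' @export
writeImagePng <- function(image, path) {
    png::writePNG(image / 255, path)
    invisible(path)
}

#' @rdname writeMaskPng
#' @export
readImagePng <- function(path) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
    img[, , 1:3, drop = FALSE] * 255
}
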