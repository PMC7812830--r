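test_that("spot quantification cancels flat background exactly", {
    roi <- SpotROI(center = c(21, 21))
    expect_equal(as.numeric(quantifySpot(matrix(0, 41, 41), roi)), 0)
    uni <- quantifySpot(matrix(7.5, 41, 41), roi)
    expect_equal(as.numeric(uni), 0)
    expect_error(quantifySpot(matrix(0, 41, 41), SpotROI(c(2, 2))),
                 "outside the image")
})

test_that("a noiseless Gaussian spot is recovered near its planted integral", {
    img <- gaussianImage(amplitude = 1000, sigma = 2, background = 50)
    q <- quantifySpot(img, SpotROI(center = c(21, 21)))
    planted <- 1000 * 2 * pi * 2^2
    expect_lt(abs(as.numeric(q) - planted) / planted, 0.1)
    expect_false(attr(q, "floored"))
})

test_that("spot quantification is linear in amplitude above background", {
    amps <- c(200, 500, 1000, 2000, 5000)
    corrected <- vapply(amps, function(a) {
        img <- gaussianImage(amplitude = a, sigma = 2, background = 100)
        as.numeric(quantifySpot(img, SpotROI(center = c(21, 21))))
    }, numeric(1))
    planted <- amps * 2 * pi * 2^2
    slope <- coef(lm(corrected ~ planted))[["planted"]]
    expect_lt(abs(slope - 1), 0.05)
})

test_that("within-spread normalization is a scale-invariant ratio", {
    expect_equal(normalizeWithinSpread(3, c(2, 4)), 1)
    expect_equal(normalizeWithinSpread(5, c(5, 5, 5)), 1)
    expect_equal(normalizeWithinSpread(30, 10 * c(2, 4)),
                 normalizeWithinSpread(3, c(2, 4)))
    expect_error(normalizeWithinSpread(1, numeric()), "at least one")
    expect_error(normalizeWithinSpread(1, c(0, 0)), "positive")
})

test_that("peak pair distance handles delta peaks and degenerate profiles", {
    x <- numeric(30); x[10] <- 1; x[20] <- 1
    d <- peakPairDistance(DotPairProfile(x, pixelSize = 0.1))
    expect_equal(as.numeric(d), 1.0)
    expect_equal(attr(d, "positionsPx"), c(10, 20))
    expect_error(peakPairDistance(DotPairProfile(1:20, pixelSize = 0.1)),
                 "single dot or no pair")
})

test_that("sub-pixel Gaussian pair separations are refined accurately", {
    x <- seq(0, 60)
    prof <- 1000 * exp(-(x - 20.2)^2 / 8) + 1000 * exp(-(x - 33.5)^2 / 8)
    d <- peakPairDistance(DotPairProfile(prof, pixelSize = 0.1,
                                         minProminence = 100))
    expect_lt(abs(as.numeric(d) / 0.1 - 13.3), 0.5)
    # literal integer-pixel mode
    d0 <- peakPairDistance(DotPairProfile(prof, 0.1, 100), refine = FALSE)
    expect_equal((as.numeric(d0) / 0.1) %% 1, 0)
})

test_that("dot patterns classify by prominence and separation", {
    x <- seq(0, 60)
    two <- 1000 * exp(-(x - 20)^2 / 8) + 1000 * exp(-(x - 30)^2 / 8)
    one <- 2000 * exp(-(x - 25)^2 / 8)
    near <- 1000 * exp(-(x - 24)^2 / 8) + 1000 * exp(-(x - 26)^2 / 8)
    set.seed(5)
    noise <- runif(61, 0, 50)
    expect_equal(classifyDotPattern(DotPairProfile(two, 0.1, 200)),
                 "two-dots")
    expect_equal(classifyDotPattern(DotPairProfile(one, 0.1, 200)),
                 "one-dot")
    # coincident-ish peaks merge into a single maximum -> one dot
    expect_equal(classifyDotPattern(DotPairProfile(near, 0.1, 200)),
                 "one-dot")
    expect_equal(classifyDotPattern(DotPairProfile(noise, 0.1, 200)),
                 "undetermined")
})

test_that("classification fractions recover a planted two-dot mixture", {
    x <- seq(0, 60)
    set.seed(11)
    piTrue <- 0.6
    n <- 120
    isTwo <- runif(n) < piTrue
    labels <- vapply(seq_len(n), function(i) {
        sep <- if (isTwo[i]) 10 else 0
        prof <- 1000 * exp(-(x - (25 - sep / 2))^2 / 8) +
            1000 * exp(-(x - (25 + sep / 2))^2 / 8) + rnorm(61, 0, 30)
        classifyDotPattern(DotPairProfile(prof, 0.1, 300))
    }, character(1))
    expect_equal(mean(labels[isTwo] == "two-dots"), 1)
    phat <- mean(labels == "two-dots")
    expect_lt(abs(phat - mean(isTwo)), 0.05)
})

test_that("measureSpread tabulates normalized intensities per spread", {
    img <- matrix(10, 120, 120)
    for (rc in list(c(30, 30, 1000), c(30, 90, 2000), c(90, 60, 1500))) {
        img <- img + gaussianImage(120, 120, rc[1], rc[2],
                                   amplitude = rc[3], sigma = 2,
                                   background = 0)
    }
    spots <- data.frame(spotId = c("neo", "ref1", "ref2"),
                        row = c(30, 30, 90), col = c(30, 90, 60),
                        reference = c(FALSE, TRUE, TRUE))
    tab <- measureSpread(img, spots)
    refMean <- mean(tab$correctedIntensity[tab$reference])
    expect_equal(tab$normalizedIntensity,
                 tab$correctedIntensity / refMean)
    # the 1000-amplitude spot sits below the reference mean of 2000/1500
    expect_lt(tab$normalizedIntensity[1], 1)
})
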