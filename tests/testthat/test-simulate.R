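test_that("configuration invariants are enforced", {
    expect_error(simulationConfig(reductionFraction = 1.2), "\\[0, 1\\]")
    expect_error(simulationConfig(domainStart = 5e8, domainEnd = 5.1e8),
                 "inside")
    expect_error(simulationConfig(domainStart = 12345, domainEnd = 1e5),
                 "multiples of binSize")
    expect_error(simulationConfig(depthMultipliers = c(1, 1, -1, 1)),
                 "positive")
    expect_error(simulationConfig(positionJitter = -1), ">= 0")
})

test_that("the same seed reproduces every simulator bit for bit", {
    cfg <- smallConfig(seed = 42)
    a <- simulateChipExperiment(cfg)
    b <- simulateChipExperiment(cfg)
    expect_identical(binValues(a$derivedIp), binValues(b$derivedIp))
    expect_identical(lapply(a$counts, targetReads),
                     lapply(b$counts, targetReads))
    c2 <- simulateChipExperiment(cfg, seed = 43)
    expect_false(identical(binValues(a$derivedIp), binValues(c2$derivedIp)))

    s1 <- simulateSvCallsets(cfg)
    s2 <- simulateSvCallsets(cfg)
    expect_identical(as.data.frame(s1$derived), as.data.frame(s2$derived))

    i1 <- simulateSpread(cfg)
    i2 <- simulateSpread(cfg)
    expect_identical(i1$image, i2$image)
    expect_false(identical(i1$image, simulateSpread(cfg, seed = 43)$image))

    # the caller's RNG stream is not consumed
    set.seed(1); before <- runif(1)
    set.seed(1); invisible(simulateChipExperiment(cfg)); after <- runif(1)
    expect_identical(before, after)
})

test_that("planted effect sizes shape the expected coverage ratio", {
    cfg0 <- smallConfig(seed = 3, reductionFraction = 0)
    expect_true(all(simulateChipExperiment(cfg0)$truth$expectedRatio == 1))
    cfg1 <- smallConfig(seed = 3, reductionFraction = 1)
    sim1 <- simulateChipExperiment(cfg1)
    tr <- sim1$truth
    starts <- binStarts(sim1$parentIp)
    inDom <- which(starts >= 1e6 & starts < 1.1e6)
    expect_equal(unique(tr$expectedRatio[inDom]), 0.5)
    expect_equal(unique(tr$expectedRatio[-inDom]), 1)
})

test_that("simulated totals scale linearly with the depth multiplier", {
    tot <- function(depth, seeds) {
        vapply(seeds, function(s) {
            cfg <- smallConfig(seed = s,
                depthMultipliers = c(parentIp = depth, parentInput = 1,
                                     derivedIp = 1, derivedInput = 1))
            targetReads(simulateChipExperiment(cfg)$counts$parentIp)
        }, numeric(1))
    }
    t1 <- tot(1, 1:12)
    t2 <- tot(2, 101:112)
    ratio <- mean(t2) / mean(t1)
    se <- ratio * sqrt(var(t1) / (12 * mean(t1)^2) +
                       var(t2) / (12 * mean(t2)^2))
    expect_lt(abs(ratio - 2), max(3 * se, 0.01))
})

test_that("SV simulation plants novel calls only in the derived set", {
    cfg <- smallConfig(seed = 8, nBackgroundSvs = 20, nNovelSvs = 4,
                       positionJitter = 3, lengthJitter = 3)
    sets <- simulateSvCallsets(cfg)
    expect_length(sets$truth, 4)
    expect_true(all(sets$truth %in% callIds(sets$derived)))
    expect_false(any(sets$truth %in% callIds(sets$parental)))
    # jitter is bounded by the configured maxima
    p <- as.data.frame(sets$parental)
    d <- as.data.frame(sets$derived)
    d <- d[match(p$id, d$id), ]
    expect_true(all(abs(d$start - p$start) <= 3))
    expect_true(all(abs(d$length - p$length) <= 3))

    # zero jitter, zero novel: subtraction of identical sets is empty
    sets0 <- simulateSvCallsets(smallConfig(seed = 9, nNovelSvs = 0,
                                            positionJitter = 0,
                                            lengthJitter = 0))
    expect_length(subtractCallsets(sets0$derived, sets0$parental), 0)
})

test_that("noiseless single spots integrate to the planted amplitude", {
    cfg <- smallConfig(seed = 4, nSpotPairs = 2, noiseSd = 0,
                       backgroundLevel = 0)
    sp <- simulateSpread(cfg)
    # with zero background and noise the image mass is the planted mass
    expect_equal(sum(sp$image), sum(sp$truth$integratedIntensity),
                 tolerance = 1e-3)
    # 1.0 um separation at 0.1 um/px plants peaks 10 px apart
    expect_equal(unique(sp$truth$separationPx), 10)
    pair <- sp$truth[sp$truth$pairId == 1, ]
    expect_equal(sqrt((pair$row[1] - pair$row[2])^2 +
                      (pair$col[1] - pair$col[2])^2), 10)
})

test_that("ground truth round-trips through the writers and readers", {
    cfg <- smallConfig(seed = 12)
    sp <- simulateSpread(cfg)
    f <- file.path(tempdir(), "truth.tsv")
    writeTruthTable(sp$truth, f)
    back <- readTruthTable(f)
    expect_equal(back, sp$truth, tolerance = 1e-12)

    sets <- simulateSvCallsets(cfg)
    f2 <- file.path(tempdir(), "sv_truth.tsv")
    writeTruthTable(data.frame(id = sets$truth), f2)
    expect_equal(readTruthTable(f2)$id, sets$truth)
})
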