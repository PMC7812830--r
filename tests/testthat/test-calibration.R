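test_that("scaling factor follows the input-corrected spike-in formula", {
    ip <- LibraryCounts("s1", "IP", targetReads = 5e6, spikeReads = 1000)
    input <- LibraryCounts("s1", "input", targetReads = 10000,
                           spikeReads = 100)
    expect_equal(factorValue(computeScalingFactor(ip, input)),
                 1e6 * (100 / 10000) / 1000)  # = 10

    # deeper input sequencing leaves the mixing estimate, hence the
    # factor, unchanged
    input2 <- LibraryCounts("s1", "input", 20000, 200)
    expect_equal(factorValue(computeScalingFactor(ip, input2)), 10)

    # invariant under doubled spike mixing (both spike totals double)
    ip3 <- LibraryCounts("s1", "IP", 5e6, 2000)
    input3 <- LibraryCounts("s1", "input", 10000, 200)
    expect_equal(factorValue(computeScalingFactor(ip3, input3)), 10)
})

test_that("scaling factor rejects invalid pairings", {
    ip <- LibraryCounts("s1", "IP", 5e6, 1000)
    other <- LibraryCounts("s2", "input", 10000, 100)
    expect_error(computeScalingFactor(ip, other), "mismatched sample ids")
    expect_error(
        computeScalingFactor(LibraryCounts("s1", "input", 10000, 100),
                             LibraryCounts("s1", "IP", 5e6, 1000)),
        "roles")
    expect_error(LibraryCounts("s1", "IP", 5e6, 0), "positive integer")
})

test_that("calibrateTrack is linear and tracks unit state", {
    raw <- CoverageTrack("chr4", 1e4, c(1, 2, 3))
    cal <- calibrateTrack(raw, unitFactor(10))
    expect_equal(binValues(cal), c(10, 20, 30))
    expect_identical(unitState(cal), "calibrated")
    expect_equal(cal@trackMeta$scalingFactor, 10)

    zero <- calibrateTrack(CoverageTrack("chr4", 1e4, numeric(5)),
                           unitFactor(7))
    expect_equal(binValues(zero), numeric(5))

    expect_error(calibrateTrack(cal, unitFactor(2)), "raw track")
})

test_that("rpkm normalization matches its closed form and invariances", {
    t1 <- CoverageTrack("chr4", 1e4, c(100, 0))
    expect_equal(binValues(rpkmNormalize(t1, 1e6)), c(10, 0))
    # doubling counts and total reads leaves RPKM unchanged
    t2 <- CoverageTrack("chr4", 1e4, c(200, 0))
    expect_equal(binValues(rpkmNormalize(t2, 2e6)),
                 binValues(rpkmNormalize(t1, 1e6)))
    expect_error(rpkmNormalize(t1, 0), "positive")
})

test_that("minmax normalization rescales, preserves order, is idempotent", {
    mm <- minmaxNormalize(CoverageTrack("chr4", 1e4, c(2, 4, 6)))
    expect_equal(binValues(mm), c(0, 0.5, 1))
    expect_identical(unitState(mm), "minmax")
    expect_equal(binValues(minmaxNormalize(mm)), binValues(mm))

    set.seed(42)
    for (i in 1:5) {
        v <- rpois(50, 20)
        if (max(v) == min(v)) next
        s <- minmaxNormalize(CoverageTrack("chr1", 1e3, v))
        expect_equal(which.max(binValues(s)), which.max(v))
        expect_equal(which.min(binValues(s)), which.min(v))
    }
    expect_error(minmaxNormalize(CoverageTrack("chr4", 1e4, rep(3, 4))),
                 "constant")
})

test_that("ratioTrack computes pseudocounted per-bin ratios", {
    parent <- calTrack(c(10, 20, 0))
    derived <- calTrack(c(10, 20, 0))
    expect_equal(ratioTrack(derived, parent, pseudocount = 1), c(1, 1, 1))
    expect_equal(ratioTrack(calTrack(0.61 * c(10, 20, 50)),
                            calTrack(c(10, 20, 50)), pseudocount = 0),
                 rep(0.61, 3))
    expect_error(ratioTrack(calTrack(1:3), calTrack(1:4)),
                 "binning mismatch")
    expect_error(
        ratioTrack(CoverageTrack("chr4", 1e4, 1:3), calTrack(1:3)),
        "calibrated")
})

test_that("calibration aligns equal-truth samples across depth and mixing", {
    # identical biology, derived sequenced 2x deeper with 2x spike mixing:
    # calibrated tracks agree bin-by-bin up to Poisson noise
    cfg <- simulationConfig(seed = 11, reductionFraction = 0,
        depthMultipliers = c(parentIp = 1, parentInput = 1,
                             derivedIp = 2, derivedInput = 2),
        spikeMix = c(parent = 0.01, derived = 0.02))
    sim <- simulateChipExperiment(cfg)
    res <- estimateAlleleReduction(sim$parentIp, sim$derivedIp, sim$counts,
                                   sim$truth$domain)
    lr <- log(binValues(res$calibrated$derived)) -
        log(binValues(res$calibrated$parent))
    expect_lt(abs(mean(lr)), 0.02)
})
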