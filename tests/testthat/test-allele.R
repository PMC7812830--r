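test_that("the two-allele deconvolution maps r to a = 2r - 1 with clipping", {
    sig <- estimateAlleleSignal(c(1, 0.61, 0.5, 0.3))
    expect_equal(alleleSignal(sig), c(1, 0.22, 0, 0))
    expect_equal(alleleSignal(sig, clipped = FALSE), c(1, 0.22, 0, -0.4))
    expect_equal(alleleRatio(sig), c(1, 0.61, 0.5, 0.3))
})

test_that("percent reduction summarizes the domain mean of a", {
    dom <- Domain("chr4", 0, 4e4)
    allOne <- estimateAlleleSignal(rep(1, 4))
    expect_equal(as.numeric(percentReduction(allOne, dom)), 0)
    allHalf <- estimateAlleleSignal(rep(0.5, 4))
    expect_equal(as.numeric(percentReduction(allHalf, dom)), 100)
    # r = 0.61 in every domain bin -> 78% reduction
    expect_equal(as.numeric(percentReduction(
        estimateAlleleSignal(rep(0.61, 4)), dom)), 78)
    # domain beyond the track is an error
    expect_error(percentReduction(allOne, Domain("chr4", 1e6, 2e6)),
                 "no complete bin")
    expect_error(percentReduction(allOne, Domain("chr7", 0, 4e4)),
                 "chromosome mismatch")
})

test_that("a is invariant under common rescaling of both calibrated tracks", {
    set.seed(7)
    v <- rpois(30, 200) + 1
    w <- rpois(30, 200) + 1
    s1 <- estimateAlleleSignal(calTrack(v), calTrack(w), pseudocount = 0)
    s2 <- estimateAlleleSignal(calTrack(5 * v), calTrack(5 * w),
                               pseudocount = 0)
    expect_equal(alleleSignal(s1), alleleSignal(s2))
})

test_that("profile report confines the dip to the domain and flags minmax", {
    r <- rep(1, 20); r[8:12] <- 0.61
    sig <- estimateAlleleSignal(r)
    dom <- Domain("chr4", 7e4, 12e4)
    rep1 <- alleleProfileReport(sig, dom, flank = 3e4)
    expect_true(attr(rep1, "minmaxApplied"))
    expect_true(all(rep1$alleleSignal[rep1$inDomain] < 1))
    expect_true(all(rep1$alleleSignal[!rep1$inDomain] == 1))
    expect_equal(range(rep1$scaledSignal), c(0, 1))

    # flat r = 1 everywhere: the minmax step degenerates and is flagged
    flat <- alleleProfileReport(estimateAlleleSignal(rep(1, 20)), dom,
                                flank = 3e4)
    expect_false(attr(flat, "minmaxApplied"))
    expect_true(all(is.na(flat$scaledSignal)))

    expect_error(alleleProfileReport(sig, dom, flank = -1), ">= 0")
})

test_that("parent measured against itself shows no reduction beyond noise", {
    cfg <- simulationConfig(seed = 21, reductionFraction = 0)
    sim <- simulateChipExperiment(cfg)
    res <- estimateAlleleReduction(sim$parentIp, sim$derivedIp, sim$counts,
                                   sim$truth$domain)
    expect_lt(abs(as.numeric(res$reduction)), 12)  # ~3 SD of the estimator
})

test_that("planted reductions are recovered without bias in expectation", {
    for (f in c(0.5, 0.78)) {
        errs <- vapply(1:25, function(s) {
            sim <- simulateChipExperiment(
                simulationConfig(seed = 400 + s, reductionFraction = f))
            res <- estimateAlleleReduction(sim$parentIp, sim$derivedIp,
                                           sim$counts, sim$truth$domain)
            as.numeric(res$reduction) - 100 * f
        }, numeric(1))
        expect_lt(abs(mean(errs)), 2.5)  # ~3.5 SE of the 25-seed mean
    }
})
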