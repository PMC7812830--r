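test_that("match tolerance branches at 250 bp and stays continuous", {
    expect_equal(matchTolerance(100), 5)
    expect_equal(matchTolerance(250), 5)       # else-branch, 250/50
    expect_equal(matchTolerance(1000), 20)
    expect_equal(matchTolerance(333), 6.66)    # fractional x kept
    # non-decreasing in parental length
    lens <- seq(0, 2000, by = 7)
    expect_true(all(diff(matchTolerance(lens)) >= 0))
    expect_error(matchTolerance(-1), ">= 0")
    # a discontinuous rule is rejected at construction
    expect_error(ToleranceRule(branchLength = 300, smallTolerance = 5,
                               divisor = 50), "continuous")
})

test_that("call matching applies the parental-length tolerance per pair", {
    expect_true(callsMatch(svCall("d", "chr4", 1000, "DEL", 100),
                           svCall("p", "chr4", 1003, "DEL", 98)))
    # type mismatch never matches, identical coordinates or not
    expect_false(callsMatch(svCall("d", "chr4", 1000, "DEL", 100),
                            svCall("p", "chr4", 1000, "INS", 100)))
    # large parental call widens the tolerance to 20
    expect_true(callsMatch(svCall("d", "chr4", 1000, "DEL", 1000),
                           svCall("p", "chr4", 1015, "DEL", 1010)))
    # short parental call keeps the tight x = 5, rejecting a 15-bp shift
    expect_false(callsMatch(svCall("d", "chr4", 1015, "DEL", 240),
                            svCall("p", "chr4", 1000, "DEL", 240)))
    # different chromosomes never match
    expect_false(callsMatch(svCall("d", "chr5", 1000, "DEL", 100),
                            svCall("p", "chr4", 1000, "DEL", 100)))
    # BND: type + position within 5, length ignored
    expect_true(callsMatch(svCall("d", "chr4", 1000, "BND", 0),
                           svCall("p", "chr4", 1004, "BND", 0)))
    expect_false(callsMatch(svCall("d", "chr4", 1000, "BND", 0),
                            svCall("p", "chr4", 1010, "BND", 0)))
})

test_that("subtraction removes matched calls and preserves order", {
    x <- makeCalls(c(1000, 5000, 9000), c("DEL", "INS", "DUP"),
                   c(100, 50, 400))
    expect_equal(length(subtractCallsets(x, x)), 0)
    expect_equal(callIds(subtractCallsets(x, SVCallSet())), callIds(x))

    derived <- makeCalls(c(1000, 5000, 43100000), c("DEL", "INS", "DEL"),
                         c(100, 50, 300), prefix = "d")
    parental <- makeCalls(c(1002, 5100), c("DEL", "INS"), c(101, 50),
                          prefix = "p")
    out <- subtractCallsets(derived, parental)
    # the INS pair is 100 bp apart, far beyond x = 5
    expect_equal(callIds(out), c("d2", "d3"))
})

test_that("subtraction is anti-monotone in the parental set", {
    set.seed(99)
    for (i in 1:20) {
        cfg <- smallConfig(seed = 500 + i,
                           nBackgroundSvs = sample(0:30, 1),
                           nNovelSvs = sample(0:10, 1),
                           positionJitter = sample(0:20, 1),
                           lengthJitter = sample(0:20, 1))
        sets <- simulateSvCallsets(cfg)
        extra <- simulateSvCallsets(smallConfig(seed = 900 + i,
                                                nBackgroundSvs = 10))
        bigger <- SVCallSet(rbind(as.data.frame(sets$parental),
            transform(as.data.frame(extra$parental),
                      id = paste0("x", id))))
        out1 <- subtractCallsets(sets$derived, sets$parental)
        out2 <- subtractCallsets(sets$derived, bigger)
        expect_true(all(callIds(out2) %in% callIds(out1)))
    }
})

test_that("jitter above every tolerance leaks background calls through", {
    # background DELs of length < 250 (x = 5) moved by 30 bp: all leak
    parental <- makeCalls(c(1000, 2000, 3000), "DEL", c(100, 120, 140),
                          prefix = "p")
    derived <- makeCalls(c(1030, 2030, 3030), "DEL", c(100, 120, 140),
                         prefix = "d")
    novel <- svCall("novel1", "chr4", 9000, "INS", 60)
    all <- SVCallSet(rbind(as.data.frame(derived), as.data.frame(novel)))
    out <- subtractCallsets(all, parental)
    expect_setequal(callIds(out), c("d1", "d2", "d3", "novel1"))
})

test_that("filters use inclusive thresholds and region overlap", {
    calls <- SVCallSet(data.frame(
        id = paste0("c", 1:5), chrom = "chr4",
        start = c(100, 200, 300, 39999000, 43100000),
        svtype = c("DEL", "DEL", "INS", "DEL", "DEL"),
        length = c(10, 9, 50, 5000, 300),
        support = c(5, 10, 4, 8, 20)))
    kept <- filterCalls(calls)
    expect_equal(callIds(kept), c("c1", "c4", "c5"))  # c2 len 9, c3 sup 4

    # region filter: c4 starts before 40 Mb but its interval reaches in
    reg <- filterCalls(calls, region = "chr4:40000000-60000000")
    expect_equal(callIds(reg), c("c4", "c5"))
    expect_error(filterCalls(calls, region = "chr4:100-50"), "inverted")
})

test_that("neocentromere-window inspection retains only overlapping calls", {
    calls <- makeCalls(c(43100000, 43300000, 42999990), "DEL",
                       c(300, 300, 5), prefix = "c")
    out <- inspectRegion(calls)
    # c1 inside; c3 starts before the window but spans into it? (42999990 +
    # 5 - 1 = 42999994 < 43000000, so no); c2 beyond the window end
    expect_equal(callIds(out), "c1")
    expect_match(attr(out, "report"), "c1\tchr4:43100000\tDEL")
    expect_length(attr(inspectRegion(SVCallSet()), "report"), 0)
})

test_that("grouped subtraction agrees with the brute-force oracle", {
    set.seed(1234)
    for (i in 1:60) {
        cfg <- smallConfig(seed = 2000 + i,
                           nBackgroundSvs = sample(0:40, 1),
                           nNovelSvs = sample(0:10, 1),
                           positionJitter = sample(0:30, 1),
                           lengthJitter = sample(0:30, 1))
        sets <- simulateSvCallsets(cfg)
        got <- callIds(subtractCallsets(sets$derived, sets$parental))
        expect_identical(got, oracleSubtract(sets$derived, sets$parental))
    }
})

test_that("SV callsets round-trip through VCF and TSV", {
    calls <- SVCallSet(data.frame(
        id = c("a", "b", "c"), chrom = "chr4",
        start = c(1000, 5000, 43100000),
        svtype = c("DEL", "INS", "BND"),
        length = c(100, 50, 0), support = c(12, 7, 5)))
    vcf <- file.path(tempdir(), "calls.vcf")
    writeSvVcf(calls, vcf)
    back <- readSvVcf(vcf)
    expect_equal(as.data.frame(back), as.data.frame(calls))

    tsv <- file.path(tempdir(), "calls.tsv")
    writeSvTsv(calls, tsv)
    expect_equal(as.data.frame(readSvTsv(tsv)), as.data.frame(calls))

    # empty set round trip
    writeSvVcf(SVCallSet(), vcf)
    expect_equal(length(readSvVcf(vcf)), 0)
})
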