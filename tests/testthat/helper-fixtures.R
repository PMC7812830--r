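# Small-scale configurations and hand-built objects shared across tests.

# A short chromosome keeps unit tests fast; the planted domain stays 10 bins.
smallConfig <- function(seed = 1, ...) {
    simulationConfig(seed = seed, chromLength = 2e6, domainStart = 1e6,
                     domainEnd = 1.1e6, ...)
}

unitFactor <- function(value = 1, sampleId = "x") {
    new("ScalingFactor", sampleId = sampleId, value = value)
}

calTrack <- function(values, chrom = "chr4", binSize = 1e4) {
    CoverageTrack(chrom, binSize, values, unitState = "calibrated")
}

makeCalls <- function(start, svtype, length, chrom = "chr4",
                      support = 10, prefix = "c") {
    n <- length(start)
    SVCallSet(data.frame(
        id = sprintf("%s%d", prefix, seq_len(n)), chrom = chrom,
        start = start, svtype = svtype,
        length = length, support = rep_len(support, n),
        stringsAsFactors = FALSE))
}

# Brute-force all-pairs subtraction oracle, independent of the package's
# grouped implementation: re-evaluates the tolerance rule inline per pair.
oracleSubtract <- function(derived, parental) {
    d <- as.data.frame(derived)
    p <- as.data.frame(parental)
    if (!nrow(d) || !nrow(p)) return(d$id)
    keep <- logical(nrow(d))
    for (i in seq_len(nrow(d))) {
        matched <- FALSE
        for (j in seq_len(nrow(p))) {
            if (d$chrom[i] != p$chrom[j] || d$svtype[i] != p$svtype[j]) next
            if (p$svtype[j] == "BND") {
                if (abs(d$start[i] - p$start[j]) <= 5) matched <- TRUE
            } else {
                x <- if (p$length[j] < 250) 5 else p$length[j] / 50
                if (abs(d$start[i] - p$start[j]) <= x &&
                    abs(d$length[i] - p$length[j]) <= x) matched <- TRUE
            }
            if (matched) break
        }
        keep[i] <- !matched
    }
    d$id[keep]
}

# Noiseless image with one centered Gaussian spot.
gaussianImage <- function(nrow = 41, ncol = 41, r0 = 21, c0 = 21,
                          amplitude = 1000, sigma = 2, background = 0) {
    outer(seq_len(nrow), seq_len(ncol), function(r, c)
        background + amplitude * exp(-((r - r0)^2 + (c - c0)^2) /
                                     (2 * sigma^2)))
}
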