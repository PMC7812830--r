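## Synthetic-data generators: every input the pipeline consumes, with known
## ground truth. All randomness flows through the explicit seed; the
## caller's RNG state is left untouched.

.withSeed <- function(seed, code) {
    hadSeed <- exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)
    old <- if (hadSeed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (hadSeed) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(code)
}

.nbinsOf <- function(config) ceiling(config@chromLength / config@binSize)

.domainBins <- function(config) {
    ## bins fully inside the planted domain (domain is bin-aligned)
    (config@domainStart / config@binSize + 1):
        (config@domainEnd / config@binSize)
}

#' Planted domain of a simulation configuration
#'
#' @param config a [SimulationConfig-class].
#' @return The planted [Domain-class].
#' @export
truthDomain <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    Domain(config@chromName, config@domainStart, config@domainEnd,
           nBins = length(.domainBins(config)))
}

#' Simulate a spike-in calibrated ChIP experiment
#'
#' Generates the four libraries of a two-line quantitative ChIP design
#' (parent IP + input, derived IP + input) for a diploid locus where the
#' engineered allele loses a fraction `f` of the chromatin mark inside the
#' planted domain. Under the equal-allele model the expected calibrated
#' derived:parent ratio is 1 outside the domain and `1 - f/2` inside it.
#'
#' Per-bin IP counts are Poisson around
#' `baseSignal * truth * depth * ipEfficiency` (truth = 1 outside, `1 - f/2`
#' inside the domain for the derived line). Library totals: IP target reads
#' are the column sums of the simulated track; input target reads are
#' Poisson with mean `depth * baseSignal * nbins`; spike-in totals are
#' Poisson with mean `spikeMix * depth * baseSignal * nbins` (times the IP
#' efficiency for IP libraries, since spike chromatin is pulled down with
#' the same antibody).
#'
#' @param config a [SimulationConfig-class].
#' @param seed overrides `config@seed`.
#' @return List with elements `parentIp` and `derivedIp` (raw
#'   [CoverageTrack-class]), `counts` (named list of four
#'   [LibraryCounts-class]: parentIp, parentInput, derivedIp,
#'   derivedInput), `truth` (list with `reductionFraction`, `domain`,
#'   `expectedRatio` per bin) and `config`.
#' @examples
#' sim <- simulateChipExperiment(simulationConfig(seed = 7,
#'     chromLength = 2e6, domainStart = 1e6, domainEnd = 1.1e6))
#' @export
simulateChipExperiment <- function(config, seed = config@seed) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    nb <- .nbinsOf(config)
    truth <- rep(1, nb)
    truth[.domainBins(config)] <- 1 - config@reductionFraction / 2
    dm <- config@depthMultipliers
    mix <- config@spikeMix
    eff <- config@ipEfficiency
    base <- config@baseSignal
    chromatin <- base * nb          # expected target reads at unit depth

    .withSeed(seed, {
        parentVals <- stats::rpois(nb, base * dm[["parentIp"]] *
                                       eff[["parent"]])
        derivedVals <- stats::rpois(nb, base * truth * dm[["derivedIp"]] *
                                        eff[["derived"]])
        pois1 <- function(mu) max(1, stats::rpois(1L, mu))
        counts <- list(
            parentIp = LibraryCounts("parent", "IP",
                targetReads = max(1, sum(parentVals)),
                spikeReads = pois1(mix[["parent"]] * dm[["parentIp"]] *
                                   eff[["parent"]] * chromatin)),
            parentInput = LibraryCounts("parent", "input",
                targetReads = pois1(dm[["parentInput"]] * chromatin),
                spikeReads = pois1(mix[["parent"]] * dm[["parentInput"]] *
                                   chromatin)),
            derivedIp = LibraryCounts("derived", "IP",
                targetReads = max(1, sum(derivedVals)),
                spikeReads = pois1(mix[["derived"]] * dm[["derivedIp"]] *
                                   eff[["derived"]] * chromatin)),
            derivedInput = LibraryCounts("derived", "input",
                targetReads = pois1(dm[["derivedInput"]] * chromatin),
                spikeReads = pois1(mix[["derived"]] * dm[["derivedInput"]] *
                                   chromatin)))
        list(parentIp = CoverageTrack(config@chromName, config@binSize,
                                      parentVals, "raw",
                                      trackMeta = list(sample = "parent")),
             derivedIp = CoverageTrack(config@chromName, config@binSize,
                                       derivedVals, "raw",
                                       trackMeta = list(sample = "derived")),
             counts = counts,
             truth = list(reductionFraction = config@reductionFraction,
                          domain = truthDomain(config),
                          expectedRatio = truth),
             config = config)
    })
}

#' Simulate a single-sample enrichment track
#'
#' Companion generator for the domain caller: Poisson counts around
#' `baseSignal`, multiplied by `enrichment` inside the planted domain
#' (`enrichment = 1` gives a pure-noise track).
#'
#' @param config a [SimulationConfig-class].
#' @param enrichment fold enrichment of the planted domain (default 10).
#' @param seed overrides `config@seed`.
#' @return List with `track` (raw [CoverageTrack-class]) and `truth`
#'   (the planted [Domain-class], or NULL when `enrichment == 1`).
#' @export
simulateEnrichmentTrack <- function(config, enrichment = 10,
                                    seed = config@seed) {
    stopifnot(is(config, "SimulationConfig"), enrichment >= 1)
    nb <- .nbinsOf(config)
    mu <- rep(config@baseSignal, nb)
    mu[.domainBins(config)] <- config@baseSignal * enrichment
    .withSeed(seed, {
        list(track = CoverageTrack(config@chromName, config@binSize,
                                   stats::rpois(nb, mu), "raw"),
             truth = if (enrichment > 1) truthDomain(config) else NULL)
    })
}

.randomSvCalls <- function(n, prefix, config) {
    if (n == 0) return(emptySvCalls())
    types <- sample(c("INS", "DEL", "DUP", "INV"), n, replace = TRUE,
                    prob = c(0.4, 0.4, 0.1, 0.1))
    data.frame(id = sprintf("%s_%d", prefix, seq_len(n)),
               chrom = config@chromName,
               start = sample.int(config@chromLength - 1e5, n) + 1,
               svtype = types,
               length = round(10^stats::runif(n, 1, 4)),   # 10 bp - 10 kb
               support = 5 + stats::rpois(n, 10),
               stringsAsFactors = FALSE)
}

#' Simulate parental and derived SV callsets with known novel calls
#'
#' Background calls are shared between the parental and derived callsets;
#' the derived copy of each background call has its start and length
#' perturbed by integer jitters drawn uniformly from
#' `[-positionJitter, positionJitter]` and `[-lengthJitter, lengthJitter]`.
#' Novel calls appear only in the derived set; their ids are the ground
#' truth that [subtractCallsets()] should recover.
#'
#' @param config a [SimulationConfig-class].
#' @param seed overrides `config@seed`.
#' @return List with `parental` and `derived` ([SVCallSet-class]) and
#'   `truth` (character vector of derived-only call ids).
#' @export
simulateSvCallsets <- function(config, seed = config@seed) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    .withSeed(seed, {
        bg <- .randomSvCalls(config@nBackgroundSvs, "bg", config)
        novel <- .randomSvCalls(config@nNovelSvs, "novel", config)
        derivedBg <- bg
        if (nrow(bg)) {
            pj <- as.integer(config@positionJitter)
            lj <- as.integer(config@lengthJitter)
            jit <- function(n, j) if (j > 0)
                sample(seq(-j, j), n, replace = TRUE) else integer(n)
            derivedBg$start <- pmax(1, bg$start + jit(nrow(bg), pj))
            derivedBg$length <- pmax(1, bg$length + jit(nrow(bg), lj))
        }
        derived <- rbind(derivedBg, novel)
        if (nrow(derived))
            derived <- derived[order(derived$start), , drop = FALSE]
        list(parental = SVCallSet(bg), derived = SVCallSet(derived),
             truth = novel$id)
    })
}

.renderSpot <- function(image, r0, c0, amplitude, sigma) {
    half <- ceiling(6 * sigma)
    rows <- max(1, floor(r0) - half):min(nrow(image), ceiling(r0) + half)
    cols <- max(1, floor(c0) - half):min(ncol(image), ceiling(c0) + half)
    g <- outer(rows, cols, function(r, c)
        amplitude * exp(-((r - r0)^2 + (c - c0)^2) / (2 * sigma^2)))
    image[rows, cols] <- image[rows, cols] + g
    image
}

#' Simulate a mitotic-spread image of Gaussian dot pairs
#'
#' Places `nSpotPairs` pairs of isotropic Gaussian spots (width
#' `spotSigma` px, peak amplitude `spotAmplitude`) on a flat
#' `backgroundLevel` with additive Gaussian noise of SD `noiseSd`. Pair
#' centers sit on a grid with random sub-pixel jitter and random pair
#' orientation; the planted separation is `spotSeparation / pixelSize`
#' pixels. The truth table lists every planted value.
#'
#' @param config a [SimulationConfig-class].
#' @param seed overrides `config@seed`.
#' @return List with `image` (numeric matrix) and `truth` (data.frame with
#'   columns `pairId`, `spotId`, `row`, `col`, `amplitude`,
#'   `integratedIntensity` (`amplitude * 2 pi sigma^2`), `separationPx`,
#'   `separationUm`).
#' @export
simulateSpread <- function(config, seed = config@seed) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    nPairs <- as.integer(config@nSpotPairs)
    sepPx <- config@spotSeparation / config@pixelSize
    cell <- max(48, ceiling(sepPx) + 40)   # room for ROI boxes + frame
    nCols <- ceiling(sqrt(nPairs))
    nRows <- ceiling(nPairs / nCols)
    image <- matrix(config@backgroundLevel, nrow = nRows * cell,
                    ncol = nCols * cell)
    .withSeed(seed, {
        rows <- numeric(0); cols <- numeric(0)
        truth <- NULL
        for (k in seq_len(nPairs)) {
            gr <- (k - 1) %/% nCols
            gc <- (k - 1) %% nCols
            ctr <- c(gr * cell + cell / 2, gc * cell + cell / 2) +
                stats::runif(2, -3, 3)
            theta <- stats::runif(1, 0, pi)
            d <- c(sin(theta), cos(theta)) * sepPx / 2
            for (s in 1:2) {
                p <- if (s == 1) ctr - d else ctr + d
                image <- .renderSpot(image, p[1], p[2],
                                     config@spotAmplitude,
                                     config@spotSigma)
                truth <- rbind(truth, data.frame(
                    pairId = k, spotId = (k - 1) * 2 + s,
                    row = p[1], col = p[2],
                    amplitude = config@spotAmplitude,
                    integratedIntensity = config@spotAmplitude *
                        2 * pi * config@spotSigma^2,
                    separationPx = sepPx,
                    separationUm = config@spotSeparation))
            }
        }
        if (config@noiseSd > 0)
            image <- image + matrix(stats::rnorm(length(image), 0,
                                                 config@noiseSd),
                                    nrow(image), ncol(image))
        list(image = image, truth = truth)
    })
}

#' Profile through a simulated dot pair
#'
#' Draws the line profile through both spots of one simulated pair,
#' extending `margin` pixels beyond each spot center, ready for
#' [peakPairDistance()].
#'
#' @param image matrix from [simulateSpread()].
#' @param truth its truth table.
#' @param pairId which pair.
#' @param pixelSize micrometres per pixel.
#' @param minProminence passed to [DotPairProfile()].
#' @param margin extension beyond each center in px (default 6).
#' @return A [DotPairProfile-class].
#' @export
pairProfile <- function(image, truth, pairId, pixelSize,
                        minProminence = 0, margin = 6) {
    spots <- truth[truth$pairId == pairId, , drop = FALSE]
    stopifnot(nrow(spots) == 2L)
    p1 <- c(spots$row[1], spots$col[1])
    p2 <- c(spots$row[2], spots$col[2])
    u <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
    DotPairProfile(lineProfile(image, p1 - margin * u, p2 + margin * u),
                   pixelSize = pixelSize, minProminence = minProminence)
}
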