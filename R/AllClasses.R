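#' @import methods
NULL

## ---------------------------------------------------------------------------
## Coverage
## ---------------------------------------------------------------------------

#' CoverageTrack: fixed-width binned per-chromosome signal
#'
#' A single-chromosome signal track of fixed-width bins starting at position 0
#' (0-based, half-open intervals, bedGraph convention). The `unitState` slot
#' declares the transform history of the values: `"raw"` binned read counts,
#' `"rpkm"` reads per kilobase per million, `"calibrated"` spike-in calibrated
#' counts, or `"minmax"` values rescaled to `[0, 1]`.
#'
#' @slot chrom chromosome name.
#' @slot binSize bin width in bp.
#' @slot values one numeric value per bin, bin `i` covering
#'   `[(i-1)*binSize, i*binSize)`.
#' @slot unitState one of `"raw"`, `"rpkm"`, `"calibrated"`, `"minmax"`.
#' @slot trackMeta free-form list of provenance metadata (e.g. the scaling
#'   factor applied by [calibrateTrack()]).
#'
#' @seealso [calibrateTrack()], [rpkmNormalize()], [minmaxNormalize()],
#'   [ratioTrack()]
#' @export
setClass("CoverageTrack",
    slots = c(chrom = "character", binSize = "numeric", values = "numeric",
              unitState = "character", trackMeta = "list"),
    prototype = prototype(unitState = "raw", trackMeta = list()))

.validCoverageTrack <- function(object) {
    msg <- NULL
    if (length(object@chrom) != 1L || !nzchar(object@chrom))
        msg <- c(msg, "'chrom' must be a single non-empty string")
    if (length(object@binSize) != 1L || !is.finite(object@binSize) ||
        object@binSize <= 0)
        msg <- c(msg, "'binSize' must be a single positive number")
    if (length(object@unitState) != 1L ||
        !object@unitState %in% c("raw", "rpkm", "calibrated", "minmax"))
        msg <- c(msg, "'unitState' must be one of raw/rpkm/calibrated/minmax")
    if (anyNA(object@values)) {
        msg <- c(msg, "'values' must not contain NA")
    } else if (length(object@values)) {
        if (identical(object@unitState, "minmax")) {
            if (min(object@values) < -1e-9 || max(object@values) > 1 + 1e-9)
                msg <- c(msg, "minmax values must lie in [0, 1]")
            if (abs(min(object@values)) > 1e-9 ||
                abs(max(object@values) - 1) > 1e-9)
                msg <- c(msg, "minmax tracks must attain exactly 0 and 1")
        } else if (min(object@values) < 0) {
            msg <- c(msg, "values must be non-negative")
        }
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("CoverageTrack", .validCoverageTrack)

#' Construct a CoverageTrack
#'
#' @param chrom chromosome name.
#' @param binSize bin width in bp.
#' @param values numeric vector, one value per bin.
#' @param unitState unit state of `values` (default `"raw"`).
#' @param trackMeta optional list of metadata.
#' @return A [CoverageTrack-class] object.
#' @examples
#' CoverageTrack("chr4", 10000, c(5, 8, 2))
#' @export
CoverageTrack <- function(chrom, binSize, values, unitState = "raw",
                          trackMeta = list()) {
    new("CoverageTrack", chrom = as.character(chrom),
        binSize = as.numeric(binSize), values = as.numeric(values),
        unitState = unitState, trackMeta = trackMeta)
}

## ---------------------------------------------------------------------------
## Library counts and scaling factors
## ---------------------------------------------------------------------------

#' LibraryCounts: per-library read totals split by genome
#'
#' Total mapped read counts for one sequencing library, split between the
#' target (human) genome and the exogenous spike-in (mouse) genome. An IP
#' library and its matched input, sharing a `sampleId`, drive the spike-in
#' calibration factor.
#'
#' @slot sampleId sample identifier shared between an IP and its input.
#' @slot role `"IP"` or `"input"`.
#' @slot targetReads reads mapped to the target genome (Nh).
#' @slot spikeReads reads mapped to the spike-in genome (Ns).
#' @seealso [computeScalingFactor()]
#' @export
setClass("LibraryCounts",
    slots = c(sampleId = "character", role = "character",
              targetReads = "numeric", spikeReads = "numeric"))

setValidity("LibraryCounts", function(object) {
    msg <- NULL
    if (length(object@sampleId) != 1L || !nzchar(object@sampleId))
        msg <- c(msg, "'sampleId' must be a single non-empty string")
    if (length(object@role) != 1L || !object@role %in% c("IP", "input"))
        msg <- c(msg, "'role' must be \"IP\" or \"input\"")
    for (s in c("targetReads", "spikeReads")) {
        v <- slot(object, s)
        if (length(v) != 1L || !is.finite(v) || v <= 0 || v != round(v))
            msg <- c(msg, sprintf("'%s' must be a single positive integer", s))
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct LibraryCounts
#'
#' @param sampleId sample identifier.
#' @param role `"IP"` or `"input"`.
#' @param targetReads,spikeReads positive integer read totals for the target
#'   and spike-in genomes.
#' @return A [LibraryCounts-class] object.
#' @examples
#' LibraryCounts("parent", "IP", targetReads = 1e7, spikeReads = 1e5)
#' @export
LibraryCounts <- function(sampleId, role, targetReads, spikeReads) {
    new("LibraryCounts", sampleId = as.character(sampleId), role = role,
        targetReads = as.numeric(targetReads),
        spikeReads = as.numeric(spikeReads))
}

#' ScalingFactor: spike-in calibration factor for one sample
#'
#' @slot sampleId sample the factor belongs to.
#' @slot value positive multiplier applied to raw IP bin counts.
#' @seealso [computeScalingFactor()], [calibrateTrack()]
#' @export
setClass("ScalingFactor",
    slots = c(sampleId = "character", value = "numeric"))

setValidity("ScalingFactor", function(object) {
    if (length(object@value) != 1L || !is.finite(object@value) ||
        object@value <= 0)
        return("'value' must be a single positive number")
    TRUE
})

## ---------------------------------------------------------------------------
## Allele-specific signal
## ---------------------------------------------------------------------------

#' AlleleSignal: per-bin estimate of the engineered allele's remaining signal
#'
#' Holds the per-bin calibrated derived:parent ratio `r` and the derived
#' allele-specific estimate `a = 2 r - 1`, interpreted as the fraction of
#' one-parental-allele signal remaining on the engineered homolog. `signal`
#' is clipped below at 0; `signalRaw` keeps the unclipped values for
#' diagnostics.
#'
#' @slot chrom,binSize binning, as in [CoverageTrack-class].
#' @slot ratio per-bin calibrated derived:parent ratio.
#' @slot signal per-bin `max(2 r - 1, 0)`.
#' @slot signalRaw per-bin unclipped `2 r - 1`.
#' @slot provenance list recording input track identities and pseudocount.
#' @seealso [estimateAlleleSignal()], [percentReduction()]
#' @export
setClass("AlleleSignal",
    slots = c(chrom = "character", binSize = "numeric", ratio = "numeric",
              signal = "numeric", signalRaw = "numeric",
              provenance = "list"))

setValidity("AlleleSignal", function(object) {
    msg <- NULL
    if (length(object@signal) != length(object@ratio) ||
        length(object@signalRaw) != length(object@ratio))
        msg <- c(msg, "'ratio', 'signal' and 'signalRaw' lengths differ")
    if (length(object@signal) && min(object@signal) < 0)
        msg <- c(msg, "'signal' must be clipped at 0")
    if (is.null(msg)) TRUE else msg
})

## ---------------------------------------------------------------------------
## Structural variants
## ---------------------------------------------------------------------------

.svTypes <- c("INS", "DEL", "DUP", "INV", "BND")
.svColumns <- c("id", "chrom", "start", "svtype", "length", "support")

#' SVCallSet: a set of typed structural-variant calls
#'
#' A thin S4 container around a data.frame of SV records with columns `id`,
#' `chrom`, `start` (1-based), `svtype` (INS/DEL/DUP/INV/BND), `length`
#' (bp, 0 for BND) and `support` (supporting reads). Row order is
#' meaningful and preserved by all operations.
#'
#' @slot calls the underlying data.frame.
#' @seealso [subtractCallsets()], [filterCalls()], [readSvVcf()]
#' @export
setClass("SVCallSet", slots = c(calls = "data.frame"))

setValidity("SVCallSet", function(object) {
    d <- object@calls
    msg <- NULL
    missing <- setdiff(.svColumns, names(d))
    if (length(missing))
        return(paste("missing columns:", paste(missing, collapse = ", ")))
    if (nrow(d)) {
        if (!all(d$svtype %in% .svTypes))
            msg <- c(msg, "svtype must be one of INS/DEL/DUP/INV/BND")
        if (any(d$start < 1))
            msg <- c(msg, "start must be >= 1 (1-based)")
        if (any(d$length < 0))
            msg <- c(msg, "length must be >= 0")
        if (any(d$support < 0))
            msg <- c(msg, "support must be >= 0")
        if (anyDuplicated(d$id))
            msg <- c(msg, "call ids must be unique")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct an SVCallSet
#'
#' @param calls data.frame with columns `id`, `chrom`, `start`, `svtype`,
#'   `length`, `support` (extra columns are kept).
#' @return An [SVCallSet-class].
#' @examples
#' SVCallSet(data.frame(id = "d1", chrom = "chr4", start = 43100000,
#'                      svtype = "DEL", length = 300, support = 12))
#' @export
SVCallSet <- function(calls = emptySvCalls()) {
    calls <- as.data.frame(calls)
    rownames(calls) <- NULL
    if (nrow(calls)) {
        calls$id <- as.character(calls$id)
        calls$chrom <- as.character(calls$chrom)
        calls$svtype <- as.character(calls$svtype)
    }
    new("SVCallSet", calls = calls)
}

#' @rdname SVCallSet
#' @export
emptySvCalls <- function() {
    data.frame(id = character(), chrom = character(), start = numeric(),
               svtype = character(), length = numeric(), support = numeric(),
               stringsAsFactors = FALSE)
}

#' Build a single SV call record
#'
#' Convenience constructor for a one-call [SVCallSet-class], handy when
#' evaluating [callsMatch()] on individual pairs.
#'
#' @param id call identifier.
#' @param chrom chromosome.
#' @param start 1-based start position.
#' @param svtype one of INS, DEL, DUP, INV, BND.
#' @param length SV length in bp (0 for BND).
#' @param support supporting read count.
#' @return A one-row [SVCallSet-class].
#' @export
svCall <- function(id, chrom, start, svtype, length, support = 10) {
    SVCallSet(data.frame(id = id, chrom = chrom, start = start,
                         svtype = svtype, length = length, support = support,
                         stringsAsFactors = FALSE))
}

#' ToleranceRule: adaptive SV matching tolerance
#'
#' Two calls of the same type are treated as the same variant when both their
#' start positions and lengths differ by at most `x` bp, where `x` is 5 for a
#' parental call shorter than 250 bp and `parental length / 50` otherwise.
#' The rule is continuous at the branch point (250 / 50 = 5), which the
#' validity method enforces.
#'
#' @slot branchLength length (bp) at which the rule switches branches.
#' @slot smallTolerance fixed tolerance (bp) below the branch.
#' @slot divisor length divisor above the branch.
#' @seealso [matchTolerance()], [callsMatch()]
#' @export
setClass("ToleranceRule",
    slots = c(branchLength = "numeric", smallTolerance = "numeric",
              divisor = "numeric"),
    prototype = prototype(branchLength = 250, smallTolerance = 5,
                          divisor = 50))

setValidity("ToleranceRule", function(object) {
    msg <- NULL
    for (s in c("branchLength", "smallTolerance", "divisor")) {
        v <- slot(object, s)
        if (length(v) != 1L || !is.finite(v) || v <= 0)
            msg <- c(msg, sprintf("'%s' must be a single positive number", s))
    }
    if (is.null(msg) &&
        abs(object@branchLength / object@divisor - object@smallTolerance) >
            1e-9)
        msg <- c(msg, "rule must be continuous: branchLength/divisor must equal smallTolerance")
    if (is.null(msg)) TRUE else msg
})

#' @rdname ToleranceRule-class
#' @param branchLength,smallTolerance,divisor see slots.
#' @return A [ToleranceRule-class].
#' @examples
#' ToleranceRule()            # the default x = 5 / length/50 rule
#' @export
ToleranceRule <- function(branchLength = 250, smallTolerance = 5,
                          divisor = 50) {
    new("ToleranceRule", branchLength = branchLength,
        smallTolerance = smallTolerance, divisor = divisor)
}

## ---------------------------------------------------------------------------
## Domains and frequency estimates
## ---------------------------------------------------------------------------

#' Domain: an enriched chromatin domain
#'
#' A contiguous genomic interval (0-based, half-open) of enriched signal,
#' e.g. the CENP-A domain defining a neocentromere.
#'
#' @slot chrom chromosome.
#' @slot start,end interval bounds in bp, 0-based half-open.
#' @slot meanEnrichment mean in-domain value over mean background value
#'   (NA when unknown, e.g. for a user-declared domain).
#' @slot nBins number of bins making up the domain (NA when unknown).
#' @seealso [callEnrichedDomain()], [domainMetrics()]
#' @export
setClass("Domain",
    slots = c(chrom = "character", start = "numeric", end = "numeric",
              meanEnrichment = "numeric", nBins = "integer"))

setValidity("Domain", function(object) {
    if (length(object@start) != 1L || length(object@end) != 1L ||
        object@end <= object@start || object@start < 0)
        return("need 0 <= start < end")
    TRUE
})

#' @rdname Domain-class
#' @param chrom,start,end,meanEnrichment,nBins see slots.
#' @return A [Domain-class].
#' @examples
#' Domain("chr4", 43080000, 43180000)
#' @export
Domain <- function(chrom, start, end, meanEnrichment = NA_real_,
                   nBins = NA_integer_) {
    new("Domain", chrom = as.character(chrom), start = as.numeric(start),
        end = as.numeric(end), meanEnrichment = as.numeric(meanEnrichment),
        nBins = as.integer(nBins))
}

#' FrequencyEstimate: neocentromere formation-frequency estimate
#'
#' @slot events number of formation events (isolates) observed.
#' @slot challengedCells number of cells challenged with an acentric
#'   chromosome.
#' @slot frequency `events / challengedCells`.
#' @slot upperLimit logical; TRUE when `events` counts recovered isolates
#'   rather than all formation events, making the frequency an upper-limit
#'   estimate.
#' @seealso [formationFrequency()]
#' @export
setClass("FrequencyEstimate",
    slots = c(events = "numeric", challengedCells = "numeric",
              frequency = "numeric", upperLimit = "logical"))

setValidity("FrequencyEstimate", function(object) {
    msg <- NULL
    if (object@challengedCells <= 0)
        msg <- c(msg, "'challengedCells' must be positive")
    if (object@events < 0)
        msg <- c(msg, "'events' must be >= 0")
    if (abs(object@frequency - object@events / object@challengedCells) >
        1e-12 * max(1, object@frequency))
        msg <- c(msg, "'frequency' must equal events/challengedCells")
    if (is.null(msg)) TRUE else msg
})

## ---------------------------------------------------------------------------
## Spread quantification
## ---------------------------------------------------------------------------

#' SpotROI: rectangular region of interest around a centromeric spot
#'
#' The measurement box used for manual spot quantification on mitotic
#' spreads: by default 10 pixels wide by 18 pixels tall, with background
#' estimated from a 2-pixel frame surrounding the box.
#'
#' @slot center numeric `(row, col)` pixel center of the box.
#' @slot box integer `(height, width)` of the box in pixels.
#' @slot backgroundMethod `"medianFrame"` (default), `"cornerMean"` or
#'   `"lowerQuartileMean"`.
#' @seealso [quantifySpot()]
#' @export
setClass("SpotROI",
    slots = c(center = "numeric", box = "numeric",
              backgroundMethod = "character"),
    prototype = prototype(box = c(height = 18, width = 10),
                          backgroundMethod = "medianFrame"))

setValidity("SpotROI", function(object) {
    msg <- NULL
    if (length(object@center) != 2L || anyNA(object@center))
        msg <- c(msg, "'center' must be (row, col)")
    if (length(object@box) != 2L || any(object@box < 1) ||
        any(object@box != round(object@box)))
        msg <- c(msg, "'box' must be positive integer (height, width)")
    if (!object@backgroundMethod %in%
        c("medianFrame", "cornerMean", "lowerQuartileMean"))
        msg <- c(msg, "unknown 'backgroundMethod'")
    if (is.null(msg)) TRUE else msg
})

#' @rdname SpotROI-class
#' @param center numeric `(row, col)`.
#' @param box `(height, width)` in pixels; default `c(18, 10)`.
#' @param backgroundMethod background estimator identifier.
#' @return A [SpotROI-class].
#' @examples
#' SpotROI(center = c(25, 25))
#' @export
SpotROI <- function(center, box = c(height = 18, width = 10),
                    backgroundMethod = "medianFrame") {
    box <- as.numeric(box)
    names(box) <- c("height", "width")
    new("SpotROI", center = as.numeric(center), box = box,
        backgroundMethod = backgroundMethod)
}

#' DotPairProfile: intensity samples along a line through a dot pair
#'
#' A 1-D line profile through (up to) two centromeric dots, sampled at
#' one-pixel spacing, plus the pixel size needed to convert peak-to-peak
#' distances to micrometres and the minimum peak prominence for a local
#' maximum to count as a dot.
#'
#' @slot samples ordered intensity samples.
#' @slot pixelSize micrometres per pixel.
#' @slot minProminence minimum prominence for a qualifying maximum,
#'   in intensity units.
#' @seealso [peakPairDistance()], [classifyDotPattern()]
#' @export
setClass("DotPairProfile",
    slots = c(samples = "numeric", pixelSize = "numeric",
              minProminence = "numeric"))

setValidity("DotPairProfile", function(object) {
    msg <- NULL
    if (length(object@samples) < 5L)
        msg <- c(msg, "need at least 5 samples")
    if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
        msg <- c(msg, "'pixelSize' must be a single positive number")
    if (length(object@minProminence) != 1L || object@minProminence < 0)
        msg <- c(msg, "'minProminence' must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' @rdname DotPairProfile-class
#' @param samples ordered intensity samples (>= 5).
#' @param pixelSize micrometres per pixel.
#' @param minProminence minimum qualifying peak prominence.
#' @return A [DotPairProfile-class].
#' @export
DotPairProfile <- function(samples, pixelSize, minProminence = 0) {
    new("DotPairProfile", samples = as.numeric(samples),
        pixelSize = pixelSize, minProminence = minProminence)
}

## ---------------------------------------------------------------------------
## Simulation configuration
## ---------------------------------------------------------------------------

#' SimulationConfig: ground-truth parameters for the synthetic-data module
#'
#' One configuration object drives all three simulators:
#' [simulateChipExperiment()] (spike-in calibrated ChIP of a diploid locus
#' where the engineered allele loses a chromatin mark by `reductionFraction`
#' inside the planted domain), [simulateSvCallsets()] (shared jittered
#' background SV calls plus derived-only novel calls) and [simulateSpread()]
#' (Gaussian dot pairs on a noisy background).
#'
#' @slot seed integer seed; the same seed yields bit-identical output.
#' @slot chromName,chromLength simulated chromosome (defaults: chr4,
#'   190,214,555 bp).
#' @slot binSize coverage bin width in bp (default 10,000).
#' @slot domainStart,domainEnd planted domain, 0-based half-open, bin-aligned
#'   (default a 100-kb window at 4p13).
#' @slot reductionFraction fraction `f` in `[0, 1]` of the mark lost on the
#'   engineered allele inside the domain.
#' @slot baseSignal mean reads per bin in the parent IP at unit depth.
#' @slot depthMultipliers named positive multipliers for sequencing depth of
#'   the four libraries (parentIp, parentInput, derivedIp, derivedInput).
#' @slot spikeMix named per-cell-line spike-in:target chromatin ratios
#'   (parent, derived).
#' @slot ipEfficiency named per-cell-line IP pull-down efficiencies
#'   (parent, derived).
#' @slot nBackgroundSvs,nNovelSvs counts of shared background SV calls and of
#'   derived-only novel calls.
#' @slot positionJitter,lengthJitter maximum perturbation (bp) applied to the
#'   derived copy of each background call.
#' @slot nSpotPairs number of dot pairs per simulated spread image.
#' @slot spotSeparation planted pair separation in micrometres.
#' @slot pixelSize micrometres per pixel.
#' @slot spotSigma Gaussian spot width (pixels).
#' @slot spotAmplitude,backgroundLevel,noiseSd intensity units: Gaussian peak
#'   amplitude, flat background level, additive noise standard deviation.
#' @seealso [simulationConfig()]
#' @export
setClass("SimulationConfig",
    slots = c(seed = "numeric", chromName = "character",
              chromLength = "numeric", binSize = "numeric",
              domainStart = "numeric", domainEnd = "numeric",
              reductionFraction = "numeric", baseSignal = "numeric",
              depthMultipliers = "numeric", spikeMix = "numeric",
              ipEfficiency = "numeric", nBackgroundSvs = "numeric",
              nNovelSvs = "numeric", positionJitter = "numeric",
              lengthJitter = "numeric", nSpotPairs = "numeric",
              spotSeparation = "numeric", pixelSize = "numeric",
              spotSigma = "numeric", spotAmplitude = "numeric",
              backgroundLevel = "numeric", noiseSd = "numeric"))

setValidity("SimulationConfig", function(object) {
    msg <- NULL
    f <- object@reductionFraction
    if (length(f) != 1L || is.na(f) || f < 0 || f > 1)
        msg <- c(msg, "'reductionFraction' must lie in [0, 1]")
    if (object@domainStart < 0 || object@domainEnd <= object@domainStart ||
        object@domainEnd > object@chromLength)
        msg <- c(msg, "domain must lie inside [0, chromLength)")
    if (object@domainStart %% object@binSize != 0 ||
        object@domainEnd %% object@binSize != 0)
        msg <- c(msg, "domain bounds must be multiples of binSize")
    if (length(object@depthMultipliers) != 4L ||
        any(object@depthMultipliers <= 0))
        msg <- c(msg, "'depthMultipliers' must be 4 positive values")
    if (length(object@spikeMix) != 2L || any(object@spikeMix <= 0))
        msg <- c(msg, "'spikeMix' must be 2 positive values")
    if (length(object@ipEfficiency) != 2L || any(object@ipEfficiency <= 0))
        msg <- c(msg, "'ipEfficiency' must be 2 positive values")
    if (object@nBackgroundSvs < 0 || object@nNovelSvs < 0)
        msg <- c(msg, "SV counts must be >= 0")
    if (object@positionJitter < 0 || object@lengthJitter < 0)
        msg <- c(msg, "jitters must be >= 0")
    if (object@baseSignal <= 0)
        msg <- c(msg, "'baseSignal' must be positive")
    if (object@pixelSize <= 0 || object@spotSigma <= 0 ||
        object@spotSeparation <= 0)
        msg <- c(msg, "spread geometry parameters must be positive")
    if (object@noiseSd < 0 || object@backgroundLevel < 0 ||
        object@spotAmplitude <= 0)
        msg <- c(msg, "spread intensity parameters out of range")
    if (is.null(msg)) TRUE else msg
})

#' Build a simulation configuration
#'
#' Defaults emulate the study conditions: 10-kb bins on a chromosome-4-sized
#' sequence, a 100-kb planted domain at 4p13 (43.08-43.18 Mb) losing 78% of
#' the mark on the engineered allele, ~500 reads per bin, a 1% spike-in
#' chromatin admixture, SV callsets filtered at length >= 10 / support >= 5
#' scale, and ~1 um dot pairs imaged at 0.1 um/pixel.
#'
#' @param seed integer seed used by the simulators.
#' @param chromName,chromLength,binSize,domainStart,domainEnd,reductionFraction,baseSignal,depthMultipliers,spikeMix,ipEfficiency,nBackgroundSvs,nNovelSvs,positionJitter,lengthJitter,nSpotPairs,spotSeparation,pixelSize,spotSigma,spotAmplitude,backgroundLevel,noiseSd
#'   see [SimulationConfig-class].
#' @return A [SimulationConfig-class].
#' @examples
#' cfg <- simulationConfig(seed = 1, reductionFraction = 0.78)
#' @export
simulationConfig <- function(seed = 1L,
                             chromName = "chr4",
                             chromLength = 190214555,
                             binSize = 10000,
                             domainStart = 43080000,
                             domainEnd = 43180000,
                             reductionFraction = 0.78,
                             baseSignal = 500,
                             depthMultipliers = c(parentIp = 1,
                                                  parentInput = 1,
                                                  derivedIp = 1,
                                                  derivedInput = 1),
                             spikeMix = c(parent = 0.01, derived = 0.01),
                             ipEfficiency = c(parent = 1, derived = 1),
                             nBackgroundSvs = 50,
                             nNovelSvs = 5,
                             positionJitter = 2,
                             lengthJitter = 2,
                             nSpotPairs = 8,
                             spotSeparation = 1.0,
                             pixelSize = 0.1,
                             spotSigma = 2,
                             spotAmplitude = 1000,
                             backgroundLevel = 100,
                             noiseSd = 50) {
    dm <- rep_len(as.numeric(depthMultipliers), 4L)
    names(dm) <- c("parentIp", "parentInput", "derivedIp", "derivedInput")
    if (!is.null(names(depthMultipliers)) &&
        all(names(depthMultipliers) %in% names(dm)) &&
        length(depthMultipliers) == 4L)
        dm[names(depthMultipliers)] <- depthMultipliers
    sm <- rep_len(as.numeric(spikeMix), 2L)
    names(sm) <- c("parent", "derived")
    ie <- rep_len(as.numeric(ipEfficiency), 2L)
    names(ie) <- c("parent", "derived")
    new("SimulationConfig", seed = as.numeric(seed), chromName = chromName,
        chromLength = as.numeric(chromLength), binSize = as.numeric(binSize),
        domainStart = as.numeric(domainStart),
        domainEnd = as.numeric(domainEnd),
        reductionFraction = as.numeric(reductionFraction),
        baseSignal = as.numeric(baseSignal), depthMultipliers = dm,
        spikeMix = sm, ipEfficiency = ie,
        nBackgroundSvs = as.numeric(nBackgroundSvs),
        nNovelSvs = as.numeric(nNovelSvs),
        positionJitter = as.numeric(positionJitter),
        lengthJitter = as.numeric(lengthJitter),
        nSpotPairs = as.numeric(nSpotPairs),
        spotSeparation = as.numeric(spotSeparation),
        pixelSize = as.numeric(pixelSize), spotSigma = as.numeric(spotSigma),
        spotAmplitude = as.numeric(spotAmplitude),
        backgroundLevel = as.numeric(backgroundLevel),
        noiseSd = as.numeric(noiseSd))
}
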