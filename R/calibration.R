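## Spike-in calibration and unit transforms for binned coverage.
##
## The spike-in model: reads from the exogenous genome recovered in an IP
## scale with (spike mixing ratio) x (sequencing depth) x (IP efficiency),
## while the input library estimates the mixing ratio alone. Dividing the
## input-derived mixing estimate by the IP spike reads therefore removes
## depth, mixing and pull-down efficiency in one factor, leaving tracks
## that are directly comparable across samples.

#' Compute the spike-in calibration factor for one sample
#'
#' The factor is
#' \deqn{C \cdot \frac{Ns_{input} / Nh_{input}}{Ns_{IP}}}
#' with `Ns` the spike-in read total, `Nh` the target-genome read total and
#' `C = 10^6` a readability constant. Multiplying raw IP bin counts by this
#' value yields tracks comparable across samples that differ in sequencing
#' depth and in spike-in cell mixing; the input-derived ratio corrects for
#' sample-to-sample variation in mixing.
#'
#' The factor is invariant under uniform rescaling of all four read totals
#' (depth) and under joint rescaling of both spike totals (mixing).
#'
#' @param ip [LibraryCounts-class] for the IP library.
#' @param input [LibraryCounts-class] for the matched input library
#'   (same `sampleId`).
#' @param constant readability constant C, default `1e6`.
#' @return A [ScalingFactor-class].
#' @examples
#' ip <- LibraryCounts("s1", "IP", targetReads = 5e6, spikeReads = 1000)
#' input <- LibraryCounts("s1", "input", targetReads = 10000,
#'                        spikeReads = 100)
#' factorValue(computeScalingFactor(ip, input))  # 1e6 * 0.01 / 1000 = 10
#' @export
computeScalingFactor <- function(ip, input, constant = 1e6) {
    stopifnot(is(ip, "LibraryCounts"), is(input, "LibraryCounts"))
    if (!identical(ip@sampleId, input@sampleId))
        stop("mismatched sample ids: '", ip@sampleId, "' vs '",
             input@sampleId, "'")
    if (!identical(ip@role, "IP") || !identical(input@role, "input"))
        stop("expected an IP library and an input library, got roles '",
             ip@role, "' and '", input@role, "'")
    if (ip@spikeReads <= 0)
        stop("zero spike-in reads in IP: calibration factor undefined")
    value <- constant * (input@spikeReads / input@targetReads) / ip@spikeReads
    new("ScalingFactor", sampleId = ip@sampleId, value = value)
}

#' Apply a calibration factor to a raw coverage track
#'
#' Multiplies every bin of a raw track by the sample's spike-in calibration
#' factor and marks the result `calibrated`. The factor used is recorded in
#' the track metadata.
#'
#' @param raw a [CoverageTrack-class] with `unitState == "raw"`.
#' @param factor a [ScalingFactor-class].
#' @return A calibrated [CoverageTrack-class].
#' @export
calibrateTrack <- function(raw, factor) {
    stopifnot(is(raw, "CoverageTrack"), is(factor, "ScalingFactor"))
    if (!identical(unitState(raw), "raw"))
        stop("calibrateTrack() expects a raw track, got unit state '",
             unitState(raw), "'")
    meta <- raw@trackMeta
    meta$scalingFactor <- factor@value
    meta$scalingSample <- factor@sampleId
    CoverageTrack(raw@chrom, raw@binSize, raw@values * factor@value,
                  unitState = "calibrated", trackMeta = meta)
}

#' RPKM-normalize a raw coverage track
#'
#' Converts raw bin counts to reads per kilobase per million mapped reads:
#' `value * 1e9 / (binSize * totalReads)`.
#'
#' @param raw a [CoverageTrack-class] with `unitState == "raw"`.
#' @param totalReads total mapped reads in the library (> 0).
#' @return An RPKM [CoverageTrack-class].
#' @examples
#' t <- CoverageTrack("chr4", 10000, 100)
#' binValues(rpkmNormalize(t, 1e6))  # 10 RPKM
#' @export
rpkmNormalize <- function(raw, totalReads) {
    stopifnot(is(raw, "CoverageTrack"))
    if (!identical(unitState(raw), "raw"))
        stop("rpkmNormalize() expects a raw track, got unit state '",
             unitState(raw), "'")
    if (length(totalReads) != 1L || !is.finite(totalReads) || totalReads <= 0)
        stop("'totalReads' must be a single positive number")
    meta <- raw@trackMeta
    meta$totalReads <- totalReads
    CoverageTrack(raw@chrom, raw@binSize,
                  raw@values * 1e9 / (raw@binSize * totalReads),
                  unitState = "rpkm", trackMeta = meta)
}

#' Min-max rescale a coverage track to [0, 1]
#'
#' Applies `(v - min) / (max - min)` per bin so that the minimum maps to 0
#' and the maximum to 1, the equal-scaling step used when overlaying tracks.
#' The transform is monotone (argmin/argmax preserved) and idempotent on
#' already-minmax tracks. A constant track has no defined rescaling and is
#' an error.
#'
#' @param track a [CoverageTrack-class] with at least two distinct values.
#' @return A minmax [CoverageTrack-class].
#' @examples
#' binValues(minmaxNormalize(CoverageTrack("chr4", 1e4, c(2, 4, 6))))
#' @export
minmaxNormalize <- function(track) {
    stopifnot(is(track, "CoverageTrack"))
    v <- track@values
    if (length(v) < 2L)
        stop("minmaxNormalize() needs at least 2 bins")
    lo <- min(v); hi <- max(v)
    if (hi - lo <= 0)
        stop("cannot min-max normalize a constant track (max == min)")
    CoverageTrack(track@chrom, track@binSize, (v - lo) / (hi - lo),
                  unitState = "minmax", trackMeta = track@trackMeta)
}

#' Per-bin derived:parent coverage ratio
#'
#' Computes `r_b = (derived_b + pseudocount) / (parent_b + pseudocount)` for
#' two calibrated tracks on identical bins. The pseudocount (default 1
#' raw-count-equivalent) floors empty bins so the ratio is defined
#' everywhere.
#'
#' @param derived,parent calibrated [CoverageTrack-class] objects with
#'   identical chromosome, bin size and bin count.
#' @param pseudocount non-negative ratio floor, default 1.
#' @return Numeric vector of per-bin ratios.
#' @export
ratioTrack <- function(derived, parent, pseudocount = 1) {
    stopifnot(is(derived, "CoverageTrack"), is(parent, "CoverageTrack"))
    if (!identical(unitState(derived), "calibrated") ||
        !identical(unitState(parent), "calibrated"))
        stop("ratioTrack() expects two calibrated tracks")
    if (!identical(derived@chrom, parent@chrom) ||
        derived@binSize != parent@binSize ||
        length(derived@values) != length(parent@values))
        stop("binning mismatch between derived and parent tracks")
    if (pseudocount < 0) stop("'pseudocount' must be >= 0")
    (derived@values + pseudocount) / (parent@values + pseudocount)
}
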