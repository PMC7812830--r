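## CENP-A enriched-domain detection and formation-frequency arithmetic.

#' Call enriched domains from a coverage track
#'
#' A simple, fully parameterized threshold detector. Bins whose value
#' exceeds `mean + zThreshold * SD` are seeds, where mean and SD are first
#' estimated on all bins, then re-estimated once on the bins outside the
#' candidate regions (so a strong domain does not inflate its own
#' threshold). Seed bins separated by gaps of at most `mergeGapBins` bins
#' are merged into one region; regions with fewer than `minWidthBins`
#' seed bins are discarded. Domains are returned widest first, the widest
#' being the primary domain (the domain is characterized by its span, not
#' its summit).
#'
#' A constant track yields no seeds and returns an empty list (not an
#' error); a track with fewer than 10 bins is an error.
#'
#' @param track a calibrated or RPKM [CoverageTrack-class] with >= 10 bins.
#' @param zThreshold number of SDs above the background mean (default 3).
#' @param mergeGapBins maximum seed gap merged into one region (default 2).
#' @param minWidthBins minimum number of above-threshold bins per region
#'   (default 3).
#' @return List of [Domain-class] objects sorted by width, widest first.
#' @export
callEnrichedDomain <- function(track, zThreshold = 3, mergeGapBins = 2,
                               minWidthBins = 3) {
    stopifnot(is(track, "CoverageTrack"))
    if (!unitState(track) %in% c("calibrated", "rpkm", "raw"))
        stop("domain calling expects calibrated, rpkm or raw units")
    v <- track@values
    if (length(v) < 10L)
        stop("too few bins for domain calling (need >= 10)")

    seedsAt <- function(m, s) which(v > m + zThreshold * s)
    regionsOf <- function(seeds) {
        if (!length(seeds)) return(list())
        breaks <- which(diff(seeds) > mergeGapBins + 1)
        startIdx <- c(1L, breaks + 1L)
        endIdx <- c(breaks, length(seeds))
        lapply(seq_along(startIdx), function(k)
            seeds[seq(startIdx[k], endIdx[k])])
    }

    ## pass 1: global stats; pass 2: stats excluding candidate regions
    seeds1 <- seedsAt(mean(v), stats::sd(v))
    candidate <- unlist(lapply(regionsOf(seeds1), function(r)
        seq(min(r), max(r))))
    bg <- if (length(candidate)) v[-candidate] else v
    if (length(bg) < 2L) bg <- v
    seeds <- seedsAt(mean(bg), stats::sd(bg))
    regions <- Filter(function(r) length(r) >= minWidthBins,
                      regionsOf(seeds))
    if (!length(regions)) return(list())

    bgMean <- mean(bg)
    domains <- lapply(regions, function(r) {
        lo <- min(r); hi <- max(r)
        Domain(track@chrom, (lo - 1) * track@binSize, hi * track@binSize,
               meanEnrichment = mean(v[lo:hi]) /
                   (if (bgMean > 0) bgMean else NA_real_),
               nBins = hi - lo + 1L)
    })
    domains[order(vapply(domains, domainWidth, numeric(1)),
                  decreasing = TRUE)]
}

#' Width of a domain and its distance to a reference point
#'
#' `width = end - start`; `distance` is the edge-to-point distance in bp:
#' 0 when the reference point lies inside the domain, otherwise the
#' smaller of the distances to the two domain edges. Both quantities are
#' translation invariant.
#'
#' @param domain a [Domain-class].
#' @param referencePoint position in bp on the same chromosome (e.g. the
#'   edge of a deleted endogenous centromere).
#' @param chrom chromosome of the reference point; must equal the domain's
#'   chromosome (default: the domain's chromosome).
#' @return Named numeric vector `c(width = , distance = )`.
#' @examples
#' domainMetrics(Domain("chr4", 43080000, 43180000), 49e6)
#' @export
domainMetrics <- function(domain, referencePoint,
                          chrom = chromName(domain)) {
    stopifnot(is(domain, "Domain"))
    if (!identical(chrom, chromName(domain)))
        stop("reference point is on ", chrom, " but domain is on ",
             chromName(domain))
    inside <- referencePoint >= domain@start & referencePoint <= domain@end
    dist <- if (inside) 0 else min(abs(domain@start - referencePoint),
                                   abs(domain@end - referencePoint))
    c(width = domain@end - domain@start, distance = dist)
}

#' Number of cells challenged with an acentric chromosome
#'
#' Back-calculates the challenged-cell count from the total cells taken
#' into an experiment and the fraction scoring positive for the
#' centromere-deletion reporter: `round(total * fraction)`. A 0.05%
#' reporter-positive fraction of 2.5e8 starting cells gives 125,000
#' challenged cells.
#'
#' @param totalCells total starting cells (> 0).
#' @param positiveFraction reporter-positive fraction in `[0, 1]`.
#' @return Integer-valued count.
#' @examples
#' challengedCells(2.5e8, 5e-4)  # 125000
#' @export
challengedCells <- function(totalCells, positiveFraction) {
    if (length(totalCells) != 1L || totalCells <= 0)
        stop("'totalCells' must be a single positive number")
    if (length(positiveFraction) != 1L || positiveFraction < 0 ||
        positiveFraction > 1)
        stop("'positiveFraction' must lie in [0, 1]")
    round(totalCells * positiveFraction)
}

#' Neocentromere formation-frequency estimate
#'
#' `frequency = events / challengedCells`. When `events` counts recovered
#' isolates rather than every formation event (the usual situation: only
#' survivors that formed a neocentromere are observed), the estimate is an
#' upper limit and is flagged as such. One isolate among 125,000 challenged
#' cells gives 8e-6.
#'
#' @param events non-negative integer count of formation events.
#' @param challengedCells positive number of challenged cells.
#' @param upperLimit flag the estimate as an upper limit (default TRUE).
#' @return A [FrequencyEstimate-class].
#' @examples
#' frequency(formationFrequency(1, 125000))  # 8e-06
#' @export
formationFrequency <- function(events, challengedCells, upperLimit = TRUE) {
    if (length(challengedCells) != 1L || challengedCells <= 0)
        stop("'challengedCells' must be a single positive number")
    if (length(events) != 1L || events < 0)
        stop("'events' must be a single non-negative number")
    new("FrequencyEstimate", events = as.numeric(events),
        challengedCells = as.numeric(challengedCells),
        frequency = events / challengedCells,
        upperLimit = isTRUE(upperLimit))
}

#' One-line human-readable frequency report
#'
#' @param x a [FrequencyEstimate-class].
#' @return Character scalar.
#' @export
formatFrequency <- function(x) {
    stopifnot(is(x, "FrequencyEstimate"))
    sprintf("%d event%s / %s challenged cells = %.3g%s",
            as.integer(x@events), if (x@events == 1) "" else "s",
            format(x@challengedCells, big.mark = ",", scientific = FALSE),
            x@frequency,
            if (x@upperLimit) " (upper limit)" else "")
}
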