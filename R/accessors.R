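## Generics, accessors and show methods.

#' @rdname CoverageTrack-class
#' @param object,x a CoverageTrack.
#' @export
setGeneric("binValues", function(x) standardGeneric("binValues"))
#' @rdname CoverageTrack-class
#' @export
setMethod("binValues", "CoverageTrack", function(x) x@values)

#' @rdname CoverageTrack-class
#' @export
setGeneric("unitState", function(x) standardGeneric("unitState"))
#' @rdname CoverageTrack-class
#' @export
setMethod("unitState", "CoverageTrack", function(x) x@unitState)

#' @rdname CoverageTrack-class
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))
#' @rdname CoverageTrack-class
#' @export
setMethod("binSize", "CoverageTrack", function(x) x@binSize)
#' @rdname AlleleSignal-class
#' @export
setMethod("binSize", "AlleleSignal", function(x) x@binSize)

#' @rdname CoverageTrack-class
#' @export
setGeneric("chromName", function(x) standardGeneric("chromName"))
#' @rdname CoverageTrack-class
#' @export
setMethod("chromName", "CoverageTrack", function(x) x@chrom)
#' @rdname AlleleSignal-class
#' @export
setMethod("chromName", "AlleleSignal", function(x) x@chrom)
#' @rdname Domain-class
#' @param x a Domain.
#' @export
setMethod("chromName", "Domain", function(x) x@chrom)

#' @rdname CoverageTrack-class
#' @export
setGeneric("nbins", function(x) standardGeneric("nbins"))
#' @rdname CoverageTrack-class
#' @export
setMethod("nbins", "CoverageTrack", function(x) length(x@values))
#' @rdname AlleleSignal-class
#' @export
setMethod("nbins", "AlleleSignal", function(x) length(x@ratio))

#' Bin start coordinates of a track (0-based)
#'
#' @param x a [CoverageTrack-class] or [AlleleSignal-class].
#' @return Numeric vector of 0-based bin starts.
#' @export
setGeneric("binStarts", function(x) standardGeneric("binStarts"))
#' @rdname binStarts
#' @export
setMethod("binStarts", "CoverageTrack",
    function(x) (seq_along(x@values) - 1) * x@binSize)
#' @rdname binStarts
#' @export
setMethod("binStarts", "AlleleSignal",
    function(x) (seq_along(x@ratio) - 1) * x@binSize)

setMethod("show", "CoverageTrack", function(object) {
    cat(sprintf("CoverageTrack on %s: %d bins of %s bp [%s]\n",
                object@chrom, length(object@values),
                format(object@binSize, big.mark = ","), object@unitState))
    if (length(object@values))
        cat(sprintf("  values: mean %.4g, range [%.4g, %.4g]\n",
                    mean(object@values), min(object@values),
                    max(object@values)))
})

#' @rdname AlleleSignal-class
#' @param x an AlleleSignal.
#' @export
setGeneric("alleleRatio", function(x) standardGeneric("alleleRatio"))
#' @rdname AlleleSignal-class
#' @export
setMethod("alleleRatio", "AlleleSignal", function(x) x@ratio)

#' @rdname AlleleSignal-class
#' @param clipped return the 0-clipped estimate (default) or the raw values.
#' @export
setGeneric("alleleSignal",
    function(x, clipped = TRUE) standardGeneric("alleleSignal"))
#' @rdname AlleleSignal-class
#' @export
setMethod("alleleSignal", "AlleleSignal",
    function(x, clipped = TRUE) if (clipped) x@signal else x@signalRaw)

setMethod("show", "AlleleSignal", function(object) {
    cat(sprintf("AlleleSignal on %s: %d bins of %s bp\n", object@chrom,
                length(object@ratio),
                format(object@binSize, big.mark = ",")))
    if (length(object@ratio))
        cat(sprintf("  mean r = %.4f, mean a = %.4f (%d bins clipped at 0)\n",
                    mean(object@ratio), mean(object@signal),
                    sum(object@signalRaw < 0)))
})

#' @rdname ScalingFactor-class
#' @param x a ScalingFactor.
#' @export
setGeneric("factorValue", function(x) standardGeneric("factorValue"))
#' @rdname ScalingFactor-class
#' @export
setMethod("factorValue", "ScalingFactor", function(x) x@value)

#' @rdname LibraryCounts-class
#' @param x a LibraryCounts or ScalingFactor.
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname LibraryCounts-class
#' @export
setMethod("sampleId", "LibraryCounts", function(x) x@sampleId)
#' @rdname ScalingFactor-class
#' @export
setMethod("sampleId", "ScalingFactor", function(x) x@sampleId)

#' @rdname LibraryCounts-class
#' @export
setGeneric("targetReads", function(x) standardGeneric("targetReads"))
#' @rdname LibraryCounts-class
#' @export
setMethod("targetReads", "LibraryCounts", function(x) x@targetReads)

#' @rdname LibraryCounts-class
#' @export
setGeneric("spikeReads", function(x) standardGeneric("spikeReads"))
#' @rdname LibraryCounts-class
#' @export
setMethod("spikeReads", "LibraryCounts", function(x) x@spikeReads)

setMethod("show", "LibraryCounts", function(object) {
    cat(sprintf("LibraryCounts %s [%s]: target %s, spike %s (%.3f%%)\n",
                object@sampleId, object@role,
                format(object@targetReads, big.mark = ","),
                format(object@spikeReads, big.mark = ","),
                100 * object@spikeReads / object@targetReads))
})

setMethod("show", "ScalingFactor", function(object) {
    cat(sprintf("ScalingFactor for %s: %.6g\n", object@sampleId,
                object@value))
})

#' @rdname SVCallSet-class
#' @param x an SVCallSet.
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))
#' @rdname SVCallSet-class
#' @export
setMethod("calls", "SVCallSet", function(x) x@calls)

#' @rdname SVCallSet-class
#' @export
setGeneric("callIds", function(x) standardGeneric("callIds"))
#' @rdname SVCallSet-class
#' @export
setMethod("callIds", "SVCallSet", function(x) x@calls$id)

#' @rdname SVCallSet-class
#' @export
setMethod("length", "SVCallSet", function(x) nrow(x@calls))

#' @rdname SVCallSet-class
#' @param i row index.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "SVCallSet", function(x, i, j, ..., drop = FALSE) {
    SVCallSet(x@calls[i, , drop = FALSE])
})

#' @rdname SVCallSet-class
#' @param row.names,optional passed through to data.frame coercion.
#' @export
setMethod("as.data.frame", "SVCallSet",
    function(x, row.names = NULL, optional = FALSE, ...) x@calls)

setMethod("show", "SVCallSet", function(object) {
    n <- nrow(object@calls)
    cat(sprintf("SVCallSet with %d call%s\n", n, if (n == 1) "" else "s"))
    if (n) {
        tab <- table(object@calls$svtype)
        cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
            "\n", sep = "")
        print(utils::head(object@calls, 5))
        if (n > 5) cat(sprintf("  ... and %d more\n", n - 5))
    }
})

#' @rdname Domain-class
#' @export
setGeneric("domainStart", function(x) standardGeneric("domainStart"))
#' @rdname Domain-class
#' @export
setMethod("domainStart", "Domain", function(x) x@start)

#' @rdname Domain-class
#' @export
setGeneric("domainEnd", function(x) standardGeneric("domainEnd"))
#' @rdname Domain-class
#' @export
setMethod("domainEnd", "Domain", function(x) x@end)

#' @rdname Domain-class
#' @export
setGeneric("domainWidth", function(x) standardGeneric("domainWidth"))
#' @rdname Domain-class
#' @export
setMethod("domainWidth", "Domain", function(x) x@end - x@start)

#' @rdname Domain-class
#' @export
setGeneric("meanEnrichment", function(x) standardGeneric("meanEnrichment"))
#' @rdname Domain-class
#' @export
setMethod("meanEnrichment", "Domain", function(x) x@meanEnrichment)

setMethod("show", "Domain", function(object) {
    cat(sprintf("Domain %s:%s-%s (%s bp", object@chrom,
                format(object@start, big.mark = ",", scientific = FALSE),
                format(object@end, big.mark = ",", scientific = FALSE),
                format(object@end - object@start, big.mark = ",",
                       scientific = FALSE)))
    if (!is.na(object@nBins)) cat(sprintf(", %d bins", object@nBins))
    if (!is.na(object@meanEnrichment))
        cat(sprintf(", %.2fx enriched", object@meanEnrichment))
    cat(")\n")
})

#' @rdname FrequencyEstimate-class
#' @param x a FrequencyEstimate.
#' @export
setGeneric("frequency", function(x) standardGeneric("frequency"))
#' @rdname FrequencyEstimate-class
#' @export
setMethod("frequency", "FrequencyEstimate", function(x) x@frequency)

#' @rdname FrequencyEstimate-class
#' @export
setGeneric("events", function(x) standardGeneric("events"))
#' @rdname FrequencyEstimate-class
#' @export
setMethod("events", "FrequencyEstimate", function(x) x@events)

#' @rdname FrequencyEstimate-class
#' @export
setGeneric("challengedCellCount",
    function(x) standardGeneric("challengedCellCount"))
#' @rdname FrequencyEstimate-class
#' @export
setMethod("challengedCellCount", "FrequencyEstimate",
    function(x) x@challengedCells)

setMethod("show", "FrequencyEstimate", function(object) {
    cat(sprintf(
        "Formation frequency: %d event%s / %s challenged cells = %.3g%s\n",
        object@events, if (object@events == 1) "" else "s",
        format(object@challengedCells, big.mark = ",", scientific = FALSE),
        object@frequency,
        if (object@upperLimit) " (upper-limit estimate)" else ""))
})
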