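## Parental-vs-derived SV callset subtraction with adaptive tolerance.

#' Adaptive position/length matching tolerance
#'
#' Returns the distance `x` within which a derived call's start position and
#' length must both fall to be considered the same variant as a parental
#' call: `x = 5` bp when the parental SV is shorter than 250 bp, and
#' `parental length / 50` otherwise. Fractional tolerances are kept (no
#' rounding); the function is non-decreasing in length and continuous at
#' the branch point.
#'
#' @param parentalLength numeric vector of parental SV lengths (bp, >= 0).
#' @param rule a [ToleranceRule-class]; default `ToleranceRule()`.
#' @return Numeric vector of tolerances in bp.
#' @examples
#' matchTolerance(c(100, 250, 1000))  # 5, 5, 20
#' @export
matchTolerance <- function(parentalLength, rule = ToleranceRule()) {
    stopifnot(is(rule, "ToleranceRule"))
    if (any(is.na(parentalLength)) || any(parentalLength < 0))
        stop("parental SV length must be >= 0")
    ifelse(parentalLength < rule@branchLength, rule@smallTolerance,
           parentalLength / rule@divisor)
}

## Vectorized core: does each derived record match ANY parental record?
## Tolerance is computed from the PARENTAL length (asymmetric by design).
## BND records carry no meaningful length and match on type + start within
## the small tolerance only.
.matchesAny <- function(dChrom, dStart, dType, dLength, parental, rule) {
    p <- parental@calls
    cand <- p$chrom == dChrom & p$svtype == dType
    if (!any(cand)) return(FALSE)
    ps <- p$start[cand]; pl <- p$length[cand]
    if (identical(dType, "BND"))
        return(any(abs(ps - dStart) <= rule@smallTolerance))
    x <- matchTolerance(pl, rule)
    any(abs(ps - dStart) <= x & abs(pl - dLength) <= x)
}

#' Do two SV calls represent the same variant?
#'
#' Two calls are the same variant when they are of the same SV type, lie on
#' the same chromosome, and both their start positions and lengths differ
#' by at most the adaptive tolerance [matchTolerance()] computed from the
#' *parental* call's length.
#'
#' @param derived,parental one-call [SVCallSet-class] objects (see
#'   [svCall()]).
#' @param rule a [ToleranceRule-class].
#' @return Logical scalar.
#' @examples
#' callsMatch(svCall("d", "chr4", 1000, "DEL", 100),
#'            svCall("p", "chr4", 1003, "DEL", 98))   # TRUE (x = 5)
#' @export
callsMatch <- function(derived, parental, rule = ToleranceRule()) {
    stopifnot(is(derived, "SVCallSet"), is(parental, "SVCallSet"),
              length(derived) == 1L, length(parental) == 1L)
    d <- derived@calls
    .matchesAny(d$chrom, d$start, d$svtype, d$length, parental, rule)
}

#' Subtract a parental SV callset from a derived callset
#'
#' Returns every derived call that matches no parental call under the
#' adaptive tolerance rule, selecting variants present only in the derived
#' sample. Subtraction is set-like: a single parental call may eliminate
#' any number of derived calls (any-match semantics, no one-to-one
#' assignment), and the derived input order is preserved.
#'
#' @param derived,parental [SVCallSet-class] objects.
#' @param rule a [ToleranceRule-class].
#' @return The derived-only [SVCallSet-class].
#' @examples
#' d <- SVCallSet(data.frame(id = c("a", "b"), chrom = "chr4",
#'                           start = c(1000, 5000), svtype = "DEL",
#'                           length = c(100, 50), support = 10))
#' subtractCallsets(d, d)  # empty
#' @export
subtractCallsets <- function(derived, parental, rule = ToleranceRule()) {
    stopifnot(is(derived, "SVCallSet"), is(parental, "SVCallSet"),
              is(rule, "ToleranceRule"))
    d <- derived@calls
    if (!nrow(d) || !nrow(parental@calls)) return(derived)
    keep <- !vapply(seq_len(nrow(d)), function(i)
        .matchesAny(d$chrom[i], d$start[i], d$svtype[i], d$length[i],
                    parental, rule),
        logical(1))
    derived[keep]
}

## 1-based inclusive call interval: spanning types cover
## [start, start + length - 1]; insertions and breakends are points.
.callEnds <- function(d) {
    spanning <- d$svtype %in% c("DEL", "DUP", "INV")
    ifelse(spanning, d$start + pmax(d$length, 1) - 1, d$start)
}

#' Parse a samtools-style region string
#'
#' @param region `"chrom:start-end"` (1-based, inclusive; commas allowed) or
#'   a list with elements `chrom`, `start`, `end`.
#' @return List with `chrom`, `start`, `end`.
#' @examples
#' parseRegion("chr4:40,000,000-60,000,000")
#' @export
parseRegion <- function(region) {
    if (is.list(region)) {
        stopifnot(all(c("chrom", "start", "end") %in% names(region)))
        out <- region[c("chrom", "start", "end")]
    } else {
        m <- regmatches(region,
                        regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", region))[[1]]
        if (length(m) != 4L)
            stop("cannot parse region '", region,
                 "'; expected chrom:start-end")
        out <- list(chrom = m[2],
                    start = as.numeric(gsub(",", "", m[3])),
                    end = as.numeric(gsub(",", "", m[4])))
    }
    if (out$end < out$start)
        stop("inverted region: end < start")
    out
}

#' Filter SV calls on length, read support and region overlap
#'
#' Keeps calls with `length >= minLength` and `support >= minSupport`
#' (inclusive thresholds, matching minimum-length/minimum-support caller
#' semantics) and, when a region is given, whose 1-based inclusive interval
#' overlaps it. Defaults reproduce the genome-wide call filtering used for
#' nanopore SV detection (`-l 10 -s 5`).
#'
#' @param x an [SVCallSet-class].
#' @param minLength minimum SV length in bp (default 10).
#' @param minSupport minimum supporting reads (default 5).
#' @param region optional region as accepted by [parseRegion()]
#'   (e.g. `"chr4:40000000-60000000"`).
#' @return The filtered [SVCallSet-class], order preserved.
#' @export
filterCalls <- function(x, minLength = 10, minSupport = 5, region = NULL) {
    stopifnot(is(x, "SVCallSet"))
    d <- x@calls
    if (!nrow(d)) return(x)
    keep <- d$length >= minLength & d$support >= minSupport
    if (!is.null(region)) {
        rg <- parseRegion(region)
        keep <- keep & d$chrom == rg$chrom & d$start <= rg$end &
            .callEnds(d) >= rg$start
    }
    x[keep]
}

#' Report calls overlapping the neocentromere window for manual review
#'
#' Restricts a callset to the calls overlapping a focal window (default the
#' neocentromere area, chr4:43,000,000-43,250,000) and attaches a formatted
#' one-call-per-line report for individual examination.
#'
#' @param x an [SVCallSet-class].
#' @param window region string or list, 1-based inclusive.
#' @return The overlapping [SVCallSet-class], with the formatted report in
#'   attribute `"report"` (character vector, one line per call).
#' @export
inspectRegion <- function(x, window = "chr4:43000000-43250000") {
    out <- filterCalls(x, minLength = 0, minSupport = 0, region = window)
    d <- out@calls
    report <- if (nrow(d)) {
        sprintf("%s\t%s:%d\t%s\tlen=%d\tsupport=%d", d$id, d$chrom,
                as.integer(d$start), d$svtype, as.integer(d$length),
                as.integer(d$support))
    } else character()
    attr(out, "report") <- report
    out
}
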