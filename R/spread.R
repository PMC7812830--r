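## Mitotic-spread quantification: background-corrected spot intensities,
## within-spread normalization, peak-to-peak distances, dot-pattern calls.

.roiRows <- function(roi) {
    ctr <- round(roi@center)
    h <- roi@box[["height"]]
    (ctr[1] - floor((h - 1) / 2)):(ctr[1] + ceiling((h - 1) / 2))
}

.roiCols <- function(roi) {
    ctr <- round(roi@center)
    w <- roi@box[["width"]]
    (ctr[2] - floor((w - 1) / 2)):(ctr[2] + ceiling((w - 1) / 2))
}

## Pixels of the 2-px frame surrounding the ROI box, clipped to the image.
.framePixels <- function(image, rows, cols, thickness = 2L) {
    outRows <- max(1L, min(rows) - thickness):min(nrow(image),
                                                 max(rows) + thickness)
    outCols <- max(1L, min(cols) - thickness):min(ncol(image),
                                                  max(cols) + thickness)
    outer <- image[outRows, outCols, drop = FALSE]
    inner <- matrix(FALSE, length(outRows), length(outCols))
    inner[match(rows, outRows), match(cols, outCols)] <- TRUE
    outer[!inner]
}

#' Background-corrected integrated spot intensity
#'
#' Sums the pixels of the ROI box and subtracts `area * background`, the
#' background being estimated from a 2-pixel frame surrounding the box
#' (default: the frame median, robust to the spot's own tails; corner-mean
#' and lowest-quartile-mean estimators are available via the ROI's
#' `backgroundMethod`). Negative corrected intensities are floored at 0 and
#' flagged with attribute `"floored"`.
#'
#' @param image numeric matrix (rows = y, columns = x).
#' @param roi a [SpotROI-class]; the box must lie fully inside the image.
#' @return Corrected intensity (numeric scalar) with attribute `"floored"`.
#' @export
quantifySpot <- function(image, roi) {
    stopifnot(is.matrix(image), is(roi, "SpotROI"))
    rows <- .roiRows(roi)
    cols <- .roiCols(roi)
    if (min(rows) < 1 || max(rows) > nrow(image) ||
        min(cols) < 1 || max(cols) > ncol(image))
        stop("ROI box extends outside the image")
    box <- image[rows, cols, drop = FALSE]
    frame <- .framePixels(image, rows, cols)
    bg <- switch(roi@backgroundMethod,
        medianFrame = stats::median(frame),
        cornerMean = {
            corners <- c(image[max(1, min(rows) - 2), max(1, min(cols) - 2)],
                         image[max(1, min(rows) - 2),
                               min(ncol(image), max(cols) + 2)],
                         image[min(nrow(image), max(rows) + 2),
                               max(1, min(cols) - 2)],
                         image[min(nrow(image), max(rows) + 2),
                               min(ncol(image), max(cols) + 2)])
            mean(corners)
        },
        lowerQuartileMean =
            mean(frame[frame <= stats::quantile(frame, 0.25)]))
    corrected <- sum(box) - length(box) * bg
    floored <- corrected < 0
    out <- max(corrected, 0)
    attr(out, "floored") <- floored
    out
}

#' Normalize a spot intensity within its cell spread
#'
#' Signals are normalized within each spread by dividing the target spot's
#' corrected intensity by the mean corrected intensity of the reference
#' spots (e.g. random canonical centromeres of the same spread). The ratio
#' is invariant under any rescaling of the whole spread.
#'
#' @param target corrected intensity of the spot of interest.
#' @param references numeric vector of reference corrected intensities
#'   (>= 1 value, positive mean).
#' @return Normalized intensity (reference mean maps to 1).
#' @examples
#' normalizeWithinSpread(3, c(2, 4))  # 1
#' @export
normalizeWithinSpread <- function(target, references) {
    if (!length(references))
        stop("need at least one reference intensity")
    m <- mean(references)
    if (!is.finite(m) || m <= 0)
        stop("reference mean must be positive")
    target / m
}

## Local maxima with prominences. A plateau contributes its first index.
## Prominence: height minus the highest of the two minima separating the
## peak from higher terrain (or from the profile edge) on each side.
.peakTable <- function(x) {
    n <- length(x)
    if (n < 3L) return(data.frame(idx = integer(), height = numeric(),
                                  prominence = numeric()))
    idx <- which(diff(sign(diff(x))) < 0) + 1L
    ## strict rise on the left, non-rise on the right (plateau-safe)
    idx <- idx[x[idx] > x[pmax(idx - 1L, 1L)] | x[idx] > x[pmin(idx + 1L, n)]]
    if (!length(idx)) return(data.frame(idx = integer(), height = numeric(),
                                        prominence = numeric()))
    prom <- vapply(idx, function(i) {
        h <- x[i]
        left <- if (i > 1) x[seq_len(i - 1)] else numeric()
        right <- if (i < n) x[seq(i + 1, n)] else numeric()
        sideMin <- function(v, reversed) {
            if (!length(v)) return(h)   # edge: no dip on this side
            if (reversed) v <- rev(v)   # walk outward from the peak
            higher <- which(v > h)
            if (length(higher)) min(v[seq_len(higher[1] - 1)], h)
            else min(v)
        }
        h - max(sideMin(left, reversed = TRUE),
                sideMin(right, reversed = FALSE))
    }, numeric(1))
    data.frame(idx = idx, height = x[idx], prominence = prom)
}

## 3-point parabolic sub-sample refinement around index i.
.refinePeak <- function(x, i) {
    if (i <= 1L || i >= length(x)) return(i)
    denom <- x[i - 1] - 2 * x[i] + x[i + 1]
    if (denom >= 0) return(i)           # not locally concave
    delta <- 0.5 * (x[i - 1] - x[i + 1]) / denom
    i + max(-0.5, min(0.5, delta))
}

#' Peak-to-peak distance of a centromeric dot pair
#'
#' Locates the two most prominent local maxima of a line profile drawn
#' through both dots, refines each location by three-point parabolic
#' interpolation (switch off with `refine = FALSE` for literal integer-pixel
#' peak positions) and returns their distance in micrometres. Fewer than
#' two maxima clearing the profile's `minProminence` is an error (single
#' dot / no pair).
#'
#' @param profile a [DotPairProfile-class].
#' @param refine logical, apply sub-pixel parabolic refinement
#'   (default TRUE).
#' @return Distance in micrometres, with attribute `"positionsPx"` giving
#'   the two refined peak positions (pixels, 1-based).
#' @examples
#' x <- numeric(30); x[10] <- 1; x[20] <- 1
#' peakPairDistance(DotPairProfile(x, pixelSize = 0.1))  # 1 um
#' @export
peakPairDistance <- function(profile, refine = TRUE) {
    stopifnot(is(profile, "DotPairProfile"))
    x <- profile@samples
    pk <- .peakTable(x)
    pk <- pk[pk$prominence >= max(profile@minProminence,
                                  .Machine$double.eps), , drop = FALSE]
    if (nrow(pk) < 2L)
        stop("fewer than two qualifying maxima: single dot or no pair")
    top <- pk[order(-pk$prominence, -pk$height)[1:2], ]
    pos <- sort(vapply(top$idx,
                       function(i) if (refine) .refinePeak(x, i) else i,
                       numeric(1)))
    out <- (pos[2] - pos[1]) * profile@pixelSize
    attr(out, "positionsPx") <- pos
    out
}

#' Classify a dot pair as one-dot, two-dots or undetermined
#'
#' Reproduces the cytological Shugoshin localization call: `"two-dots"`
#' when two maxima clear the profile's minimum prominence and are separated
#' by at least `resolutionPx` pixels (kinetochore-biased localization),
#' `"one-dot"` when only one qualifying maximum exists or the pair is
#' unresolved, and `"undetermined"` when no maximum clears the prominence.
#'
#' @param profile a [DotPairProfile-class].
#' @param resolutionPx minimum separation (pixels) to resolve two dots
#'   (default 3).
#' @return One of `"two-dots"`, `"one-dot"`, `"undetermined"`.
#' @export
classifyDotPattern <- function(profile, resolutionPx = 3) {
    stopifnot(is(profile, "DotPairProfile"))
    x <- profile@samples
    pk <- .peakTable(x)
    pk <- pk[pk$prominence >= max(profile@minProminence,
                                  .Machine$double.eps), , drop = FALSE]
    if (nrow(pk) == 0L) return("undetermined")
    if (nrow(pk) == 1L) return("one-dot")
    top <- pk[order(-pk$prominence, -pk$height)[1:2], ]
    pos <- vapply(top$idx, function(i) .refinePeak(x, i), numeric(1))
    if (abs(diff(pos)) >= resolutionPx) "two-dots" else "one-dot"
}

#' Sample an image along a straight line
#'
#' Bilinear interpolation of pixel intensities along the segment from
#' `from` to `to` (both `(row, col)`, 1-based pixel coordinates), at
#' one-pixel spacing. Used to draw the line profile intersecting both
#' centromeric dots of a pair.
#'
#' @param image numeric matrix.
#' @param from,to numeric `(row, col)` endpoints.
#' @return Numeric vector of sampled intensities.
#' @export
lineProfile <- function(image, from, to) {
    stopifnot(is.matrix(image), length(from) == 2L, length(to) == 2L)
    len <- sqrt(sum((to - from)^2))
    if (len <= 0) stop("'from' and 'to' coincide")
    ## exactly one-pixel spacing: peak-to-peak sample distances are pixels
    steps <- seq(0, floor(len + 1e-9), by = 1)
    u <- (to - from) / len
    r <- from[1] + steps * u[1]
    c <- from[2] + steps * u[2]
    r0 <- pmin(pmax(floor(r), 1L), nrow(image) - 1L)
    c0 <- pmin(pmax(floor(c), 1L), ncol(image) - 1L)
    fr <- r - r0
    fc <- c - c0
    image[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
        image[cbind(r0 + 1, c0)] * fr * (1 - fc) +
        image[cbind(r0, c0 + 1)] * (1 - fr) * fc +
        image[cbind(r0 + 1, c0 + 1)] * fr * fc
}

#' Quantify and normalize all spots of one spread
#'
#' Convenience wrapper producing the per-spot measurement table for one
#' spread image: corrected intensity per spot (via [quantifySpot()]) and
#' within-spread normalized intensity relative to the mean of the
#' reference spots.
#'
#' @param image numeric matrix.
#' @param spots data.frame with columns `spotId`, `row`, `col` and logical
#'   `reference` (TRUE for spots forming the normalization reference).
#' @param box,backgroundMethod passed to [SpotROI()].
#' @return data.frame with columns `spotId`, `correctedIntensity`,
#'   `normalizedIntensity`, `reference`.
#' @export
measureSpread <- function(image, spots, box = c(height = 18, width = 10),
                          backgroundMethod = "medianFrame") {
    stopifnot(all(c("spotId", "row", "col", "reference") %in% names(spots)))
    corrected <- vapply(seq_len(nrow(spots)), function(i)
        as.numeric(quantifySpot(image,
            SpotROI(c(spots$row[i], spots$col[i]), box = box,
                    backgroundMethod = backgroundMethod))),
        numeric(1))
    refs <- corrected[spots$reference]
    data.frame(spotId = spots$spotId, correctedIntensity = corrected,
               normalizedIntensity = vapply(corrected,
                   normalizeWithinSpread, numeric(1), references = refs),
               reference = spots$reference)
}
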