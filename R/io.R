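## Readers and writers for the standard interchange formats: bedGraph
## coverage, TSV library counts and truth tables, VCF v4.2 SV callsets
## (INFO keys SVTYPE, SVLEN, END, RE), BED domains, plain-text or 16-bit
## TIFF images.

#' Write a coverage track as bedGraph
#'
#' Intervals are 0-based half-open. Runs of adjacent equal-value bins are
#' merged on write (run-length encoding); [readBedGraph()] expands them
#' back to fixed-width bins.
#'
#' @param track a [CoverageTrack-class].
#' @param file output path.
#' @param merge merge adjacent equal-value bins (default TRUE).
#' @return `file`, invisibly.
#' @export
writeBedGraph <- function(track, file, merge = TRUE) {
    stopifnot(is(track, "CoverageTrack"))
    starts <- binStarts(track)
    v <- binValues(track)
    if (merge && length(v) > 1) {
        r <- rle(v)
        ends <- cumsum(r$lengths) * binSize(track)
        starts <- c(0, ends[-length(ends)])
        v <- r$values
    } else {
        ends <- starts + binSize(track)
    }
    gr <- GenomicRanges::GRanges(chromName(track),
        IRanges::IRanges(start = starts + 1, end = ends), score = v)
    rtracklayer::export(gr, file, format = "bedGraph")
    invisible(file)
}

#' Read a bedGraph file into a CoverageTrack
#'
#' Expands run-length merged intervals into fixed-width bins. Intervals
#' must tile the chromosome contiguously from 0 in multiples of `binSize`.
#'
#' @param file bedGraph path.
#' @param binSize bin width in bp; when `NULL`, the greatest common divisor
#'   of the interval widths is used.
#' @param unitState unit state to stamp on the result (default `"raw"`).
#' @return A [CoverageTrack-class].
#' @export
readBedGraph <- function(file, binSize = NULL, unitState = "raw") {
    gr <- rtracklayer::import(file, format = "bedGraph")
    if (!length(gr)) stop("empty bedGraph: ", file)
    chrom <- as.character(GenomicRanges::seqnames(gr))
    if (length(unique(chrom)) != 1L)
        stop("expected a single-chromosome bedGraph")
    gr <- sort(gr)
    w <- GenomicRanges::width(gr)
    if (is.null(binSize)) {
        binSize <- Reduce(function(a, b) {
            while (b) { t <- b; b <- a %% b; a <- t }; a
        }, w)
    }
    if (any(w %% binSize != 0))
        stop("interval widths are not multiples of binSize = ", binSize)
    v <- rep(gr$score, times = w / binSize)
    CoverageTrack(chrom[1], binSize, v, unitState = unitState)
}

#' Write/read library counts as TSV
#'
#' Columns: `sample_id`, `role`, `target_reads`, `spike_reads`.
#'
#' @param counts a list of [LibraryCounts-class] (possibly named).
#' @param file TSV path.
#' @return `writeLibraryCounts`: `file` invisibly. `readLibraryCounts`: a
#'   named list of [LibraryCounts-class], names `sampleId` + `Ip`/`Input`.
#' @export
writeLibraryCounts <- function(counts, file) {
    df <- do.call(rbind, lapply(counts, function(x)
        data.frame(sample_id = x@sampleId, role = x@role,
                   target_reads = x@targetReads,
                   spike_reads = x@spikeReads)))
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' @rdname writeLibraryCounts
#' @export
readLibraryCounts <- function(file) {
    df <- utils::read.delim(file, stringsAsFactors = FALSE)
    out <- lapply(seq_len(nrow(df)), function(i)
        LibraryCounts(df$sample_id[i], df$role[i], df$target_reads[i],
                      df$spike_reads[i]))
    names(out) <- paste0(df$sample_id,
                         ifelse(df$role == "IP", "Ip", "Input"))
    out
}

#' Write an SV callset as VCF v4.2
#'
#' Records carry INFO keys `SVTYPE`, `SVLEN`, `END` and `RE` (supporting
#' reads) and symbolic ALT alleles.
#'
#' @param x an [SVCallSet-class].
#' @param file output path (`.vcf`).
#' @return `file`, invisibly.
#' @export
writeSvVcf <- function(x, file) {
    stopifnot(is(x, "SVCallSet"))
    d <- x@calls
    n <- nrow(d)
    if (n == 0) {                       # header-only VCF
        writeLines(c("##fileformat=VCFv4.2",
            "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), file)
        return(invisible(file))
    }
    rr <- GenomicRanges::GRanges(d$chrom,
        IRanges::IRanges(start = d$start, width = 1))
    names(rr) <- d$id
    fixed <- S4Vectors::DataFrame(
        REF = Biostrings::DNAStringSet(rep("N", n)),
        ALT = IRanges::CharacterList(as.list(paste0("<", d$svtype, ">"))),
        QUAL = rep(NA_real_, n),
        FILTER = rep("PASS", n))
    info <- S4Vectors::DataFrame(
        SVTYPE = d$svtype,
        SVLEN = as.integer(d$length),
        END = as.integer(.callEnds(d)),
        RE = as.integer(d$support))
    hdrInfo <- S4Vectors::DataFrame(
        Number = rep("1", 4), Type = c("String", rep("Integer", 3)),
        Description = c("Type of structural variant",
                        "Length of the SV",
                        "End position of the SV",
                        "Number of supporting reads"),
        row.names = c("SVTYPE", "SVLEN", "END", "RE"))
    hdr <- VariantAnnotation::VCFHeader(samples = character())
    VariantAnnotation::info(hdr) <- hdrInfo
    VariantAnnotation::meta(hdr) <- IRanges::DataFrameList(
        fileformat = S4Vectors::DataFrame(Value = "VCFv4.2",
                                          row.names = "fileformat"))
    vcf <- VariantAnnotation::VCF(rowRanges = rr, fixed = fixed,
        info = info, collapsed = TRUE)
    VariantAnnotation::header(vcf) <- hdr
    VariantAnnotation::writeVcf(vcf, file)
    invisible(file)
}

#' Read an SV callset from a VCF
#'
#' Understands the caller-style INFO fields `SVTYPE`, `SVLEN` (absolute
#' value used) and `RE` (supporting reads; 0 when absent).
#'
#' @param file VCF path.
#' @return An [SVCallSet-class].
#' @export
readSvVcf <- function(file) {
    vcf <- VariantAnnotation::readVcf(file)
    n <- length(vcf)
    if (n == 0) return(SVCallSet())
    info <- VariantAnnotation::info(vcf)
    rr <- SummarizedExperiment::rowRanges(vcf)
    unlist1 <- function(x, default) {
        if (is.null(x)) return(rep(default, n))
        x <- vapply(as.list(x), function(e)
            if (length(e)) as.numeric(e[[1]]) else default, numeric(1))
        x
    }
    svlen <- if ("SVLEN" %in% names(info))
        abs(unlist1(info$SVLEN, 0)) else rep(0, n)
    support <- if ("RE" %in% names(info))
        unlist1(info$RE, 0) else rep(0, n)
    svtype <- if ("SVTYPE" %in% names(info))
        as.character(info$SVTYPE) else rep("BND", n)
    SVCallSet(data.frame(
        id = names(rr), chrom = as.character(GenomicRanges::seqnames(rr)),
        start = GenomicRanges::start(rr), svtype = svtype, length = svlen,
        support = support, stringsAsFactors = FALSE))
}

#' Write/read an SV callset in the plain TSV dialect
#'
#' Columns: `id`, `chrom`, `start`, `svtype`, `length`, `support`.
#'
#' @param x an [SVCallSet-class].
#' @param file TSV path.
#' @return `writeSvTsv`: `file` invisibly; `readSvTsv`: an
#'   [SVCallSet-class].
#' @export
writeSvTsv <- function(x, file) {
    stopifnot(is(x, "SVCallSet"))
    utils::write.table(x@calls[, .svColumns], file, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' @rdname writeSvTsv
#' @export
readSvTsv <- function(file) {
    SVCallSet(utils::read.delim(file, stringsAsFactors = FALSE))
}

#' Write/read a generic truth table as TSV
#'
#' Plain tab-separated round trip for the simulators' ground-truth tables;
#' numeric columns are written with full precision.
#'
#' @param truth a data.frame.
#' @param file TSV path.
#' @return `writeTruthTable`: `file` invisibly; `readTruthTable`: a
#'   data.frame.
#' @export
writeTruthTable <- function(truth, file) {
    df <- truth
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) format(x, digits = 17,
                                                  trim = TRUE))
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' @rdname writeTruthTable
#' @export
readTruthTable <- function(file) {
    utils::read.delim(file, stringsAsFactors = FALSE)
}

#' Write domains as BED
#'
#' 0-based half-open intervals; the score column carries
#' `meanEnrichment * 100` capped at 1000 (BED convention).
#'
#' @param domains list of [Domain-class].
#' @param file BED path.
#' @return `file`, invisibly.
#' @export
writeDomainsBed <- function(domains, file) {
    lines <- vapply(seq_along(domains), function(i) {
        d <- domains[[i]]
        score <- if (is.na(d@meanEnrichment)) 0 else
            min(1000, round(d@meanEnrichment * 100))
        sprintf("%s\t%d\t%d\tdomain_%d\t%d", d@chrom,
                as.integer(d@start), as.integer(d@end), i,
                as.integer(score))
    }, character(1))
    writeLines(lines, file)
    invisible(file)
}

#' Write/read an intensity image
#'
#' Plain whitespace-separated matrix text by default; `.tif`/`.tiff` paths
#' use 16-bit grayscale TIFF (requires the `tiff` package; intensities are
#' scaled to the 16-bit range on write).
#'
#' @param image numeric matrix.
#' @param file output path.
#' @return `writeImageMatrix`: `file` invisibly; `readImageMatrix`: a
#'   numeric matrix.
#' @export
writeImageMatrix <- function(image, file) {
    stopifnot(is.matrix(image))
    if (grepl("\\.tiff?$", file, ignore.case = TRUE)) {
        if (!requireNamespace("tiff", quietly = TRUE))
            stop("TIFF output requires the 'tiff' package")
        tiff::writeTIFF(pmin(pmax(image / 65535, 0), 1), file,
                        bits.per.sample = 16L)
    } else {
        utils::write.table(format(image, digits = 17, trim = TRUE), file,
                           sep = " ", quote = FALSE, row.names = FALSE,
                           col.names = FALSE)
    }
    invisible(file)
}

#' @rdname writeImageMatrix
#' @export
readImageMatrix <- function(file) {
    if (grepl("\\.tiff?$", file, ignore.case = TRUE)) {
        if (!requireNamespace("tiff", quietly = TRUE))
            stop("TIFF input requires the 'tiff' package")
        return(tiff::readTIFF(file) * 65535)
    }
    as.matrix(utils::read.table(file, header = FALSE))
}

#' Read a simulation configuration from YAML
#'
#' Keys use snake_case matching the configuration fields (e.g.
#' `reduction_fraction`, `bin_size`, `n_background_svs`); unknown keys are
#' an error.
#'
#' @param file YAML path.
#' @return A [SimulationConfig-class].
#' @export
readSimulationConfig <- function(file) {
    cfg <- yaml::read_yaml(file)
    if (is.null(cfg)) cfg <- list()
    snake <- function(x) gsub("([A-Z])", "_\\L\\1", x, perl = TRUE)
    formalNames <- names(formals(simulationConfig))
    map <- stats::setNames(formalNames, snake(formalNames))
    unknown <- setdiff(names(cfg), c(names(map), formalNames))
    if (length(unknown))
        stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
    args <- cfg
    names(args) <- ifelse(names(cfg) %in% names(map),
                          map[names(cfg)], names(cfg))
    do.call(simulationConfig, args)
}
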