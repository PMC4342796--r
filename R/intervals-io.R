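#' Read a BED file of genomic intervals into a GRanges
#'
#' Parses BED3/BED4/BED6 text (tab-separated; columns beyond the sixth are
#' ignored; `track`, `browser` and `#` lines are skipped).  BED coordinates
#' are 0-based half-open; the returned [GenomicRanges::GRanges] uses the
#' Bioconductor 1-based closed convention, so a BED record `chr1 100 200`
#' becomes `chr1:101-200` (width 100).  The conversion happens only here and
#' in [writeBed()]; everything else in the package operates on GRanges.
#' Strand is ignored throughout: histone-mark peaks and enhancer assays are
#' strand-agnostic.
#'
#' @param path path to a BED file.
#' @param genome optional [GenomeInfoDb::Seqinfo]; when supplied, records on
#'   unknown chromosomes or exceeding chromosome bounds are an error, and the
#'   result carries the seqinfo.
#' @return a GRanges sorted by (chromosome, start, end), with BED name
#'   column (when present) as `names()`.  Duplicate identical records are
#'   retained: peak callers can emit them and deduplication is the caller's
#'   decision.
#' @examples
#' tf <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tpeak_a", tf)
#' readBed(tf)
#' @seealso [writeBed()], [readChromSizes()]
#' @export
readBed <- function(path, genome = NULL) {
    lines <- readLines(path)
    keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
    lineno <- which(keep)
    lines <- lines[keep]
    if (!length(lines)) {
        gr <- GRanges()
        if (!is.null(genome)) GenomeInfoDb::seqinfo(gr) <- genome
        return(gr)
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L))
        stop(sprintf("BED parse error at line %d: fewer than 3 columns",
                     lineno[which(nf < 3L)[1L]]))
    chrom <- vapply(fields, `[[`, character(1), 1L)
    start0 <- suppressWarnings(
        as.numeric(vapply(fields, `[[`, character(1), 2L)))
    end0 <- suppressWarnings(
        as.numeric(vapply(fields, `[[`, character(1), 3L)))
    bad <- which(is.na(start0) | is.na(end0) |
                 start0 != floor(start0) | end0 != floor(end0))
    if (length(bad))
        stop(sprintf("BED parse error at line %d: non-integer coordinates",
                     lineno[bad[1L]]))
    bad <- which(start0 < 0 | start0 >= end0)
    if (length(bad))
        stop(sprintf(
            "BED parse error at line %d: require 0 <= start < end",
            lineno[bad[1L]]))
    nm <- rep(NA_character_, length(lines))
    has4 <- nf >= 4L
    nm[has4] <- vapply(fields[has4], `[[`, character(1), 4L)
    if (!is.null(genome)) {
        unknown <- !chrom %in% GenomeInfoDb::seqnames(genome)
        if (any(unknown))
            stop(sprintf("BED bounds error at line %d: unknown chromosome %s",
                         lineno[which(unknown)[1L]],
                         chrom[which(unknown)[1L]]))
        lens <- GenomeInfoDb::seqlengths(genome)[chrom]
        over <- end0 > lens
        if (any(over))
            stop(sprintf(
                "BED bounds error at line %d: interval exceeds %s length %d",
                lineno[which(over)[1L]], chrom[which(over)[1L]],
                lens[which(over)[1L]]))
    }
    gr <- if (is.null(genome))
        GRanges(chrom, IRanges::IRanges(start = start0 + 1, end = end0))
    else
        GRanges(chrom, IRanges::IRanges(start = start0 + 1, end = end0),
                seqinfo = genome)
    if (any(!is.na(nm))) names(gr) <- nm
    sortRegions(gr)
}

#' Write a GRanges as BED text
#'
#' Emits BED3, or BED4 when the GRanges has non-NA `names()`.  Coordinates
#' are converted back to 0-based half-open, so `readBed(writeBed(x))`
#' round-trips exactly.
#'
#' @param regions a GRanges.
#' @param path output path.
#' @return the number of records written, invisibly.
#' @seealso [readBed()]
#' @export
writeBed <- function(regions, path) {
    n <- length(regions)
    if (n == 0L) {
        writeLines(character(0), path)
        return(invisible(0L))
    }
    chrom <- as.character(GenomeInfoDb::seqnames(regions))
    start0 <- format(GenomicRanges::start(regions) - 1, scientific = FALSE,
                     trim = TRUE)
    end0 <- format(GenomicRanges::end(regions), scientific = FALSE,
                   trim = TRUE)
    nm <- names(regions)
    if (!is.null(nm) && any(!is.na(nm)))
        lines <- paste(chrom, start0, end0, nm, sep = "\t")
    else
        lines <- paste(chrom, start0, end0, sep = "\t")
    writeLines(lines, path)
    invisible(n)
}

#' Read and write a chromosome-sizes table
#'
#' `readChromSizes` parses a two-column `chrom.sizes` TSV (chromosome name,
#' length in bp) into a [GenomeInfoDb::Seqinfo]; `writeChromSizes` writes
#' one.
#'
#' @param path path to the chrom.sizes file.
#' @param genome a Seqinfo.
#' @return `readChromSizes`: a Seqinfo. `writeChromSizes`: the path,
#'   invisibly.
#' @export
readChromSizes <- function(path) {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             col.names = c("chrom", "size"),
                             colClasses = c("character", "numeric"))
    if (anyDuplicated(tab$chrom)) stop("duplicate chromosome names")
    if (any(tab$size <= 0)) stop("chromosome lengths must be positive")
    Seqinfo(seqnames = tab$chrom, seqlengths = tab$size)
}

#' @rdname readChromSizes
#' @export
writeChromSizes <- function(genome, path) {
    writeLines(paste(GenomeInfoDb::seqnames(genome),
                     format(GenomeInfoDb::seqlengths(genome),
                            scientific = FALSE, trim = TRUE),
                     sep = "\t"), path)
    invisible(path)
}

#' Overlap test between query regions and a peak set
#'
#' For each query region, reports whether any peak on the same chromosome
#' shares at least `minbp` bases with it.  Built on the interval-tree search
#' of [GenomicRanges::countOverlaps()], never an all-pairs scan.  Under the
#' half-open BED view, adjacent intervals ([a,b) and [b,c)) do not overlap.
#'
#' @param query GRanges of query regions.
#' @param peaks GRanges of peaks (an empty set yields all-`FALSE`).
#' @param minbp minimum shared bases to count as an overlap (default 1, the
#'   bedtools-intersect convention).
#' @return logical vector, one element per query region.
#' @examples
#' q <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
#' p <- GenomicRanges::GRanges("chr1", IRanges::IRanges(200, 300))
#' hasOverlap(q, p)              # TRUE: 1 bp shared
#' hasOverlap(GenomicRanges::shift(q, -1), p)  # FALSE: adjacency
#' @export
hasOverlap <- function(query, peaks, minbp = 1L) {
    stopifnot(minbp >= 1L)
    GenomicRanges::countOverlaps(query, peaks, minoverlap = minbp,
                                 ignore.strand = TRUE) > 0L
}

# Sort by (chrom, start, end), chromosome names compared lexicographically;
# stable for duplicate records.
sortRegions <- function(gr) {
    o <- order(as.character(GenomeInfoDb::seqnames(gr)),
               GenomicRanges::start(gr), GenomicRanges::end(gr))
    gr[o]
}
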