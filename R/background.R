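#' Sample chromosome- and length-matched background negatives
#'
#' Generates `ratio` random negative regions for every positive region, in
#' the manner of bedtools `randomBed`: each negative lies on the same
#' chromosome as its positive, has exactly its length, stays within
#' chromosome bounds, and overlaps (by >= 1 bp) no region in `exclusions`.
#' Start positions are uniform over all valid placements, achieved by
#' rejection sampling; negatives may overlap one another (preventing
#' self-overlap would bias the placement of long regions).
#'
#' The intended exclusion set for enhancer-prediction experiments is the
#' union of all positives and all known enhancers of any tissue, so that
#' "background" means regions without known enhancer activity.
#'
#' @param positives GRanges of positive regions; each must fit on its
#'   chromosome.
#' @param genome a [GenomeInfoDb::Seqinfo] giving chromosome lengths.
#' @param exclusions GRanges that negatives must not touch (default empty).
#' @param ratio negatives per positive (default 10).
#' @param maxTries rejection-sampling attempts per negative before a
#'   sampling-exhausted error (default 1000).
#' @param seed integer seed; results are deterministic given the seed.
#' @return GRanges of `ratio * length(positives)` negatives, named
#'   `<positive name>_neg<i>` (positives are named `pos<j>` when unnamed),
#'   carrying the genome's seqinfo.
#' @examples
#' g <- GenomeInfoDb::Seqinfo("chr1", 1e6)
#' pos <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 1999))
#' neg <- sampleMatchedNegatives(pos, g, ratio = 10, seed = 1)
#' table(GenomicRanges::width(neg))   # all width 1000
#' @export
sampleMatchedNegatives <- function(positives, genome,
                                   exclusions = GRanges(),
                                   ratio = 10L, maxTries = 1000L,
                                   seed = 1L) {
    stopifnot(ratio >= 1L, maxTries >= 1L)
    lens <- GenomeInfoDb::seqlengths(genome)
    pos_chrom <- as.character(GenomeInfoDb::seqnames(positives))
    pos_w <- GenomicRanges::width(positives)
    if (any(is.na(lens[pos_chrom])))
        stop("positive on a chromosome absent from the genome")
    if (any(pos_w > lens[pos_chrom]))
        stop("positive longer than its chromosome")
    pos_nm <- names(positives)
    if (is.null(pos_nm) || any(is.na(pos_nm)))
        pos_nm <- paste0("pos", seq_along(positives))
    n_pos <- length(positives)
    if (n_pos == 0L) {
        gr <- GRanges()
        GenomeInfoDb::seqinfo(gr) <- genome
        return(gr)
    }
    n_neg <- n_pos * ratio
    neg_chrom <- rep(pos_chrom, each = ratio)
    neg_w <- rep(pos_w, each = ratio)
    neg_max_start <- rep(lens[pos_chrom] - pos_w + 1L, each = ratio)
    neg_parent <- rep(pos_nm, each = ratio)
    withSeed(seed, {
        # Batched rejection: draw all pending placements at once, keep those
        # clear of the exclusions, redraw the rest.  Uniform over valid
        # placements, identical in law to per-record rejection.
        start <- integer(n_neg)
        pending <- seq_len(n_neg)
        for (t in seq_len(maxTries)) {
            start[pending] <- runifInt(length(pending), 1L,
                                       neg_max_start[pending])
            if (!length(exclusions)) {
                pending <- integer(0)
                break
            }
            cand <- GRanges(neg_chrom[pending],
                            IRanges::IRanges(start[pending],
                                             width = neg_w[pending]))
            bad <- hasOverlap(cand, exclusions)
            pending <- pending[bad]
            if (!length(pending)) break
        }
        if (length(pending))
            stop(sprintf(
                "sampling exhausted after %d tries for positive %s",
                maxTries, neg_parent[pending[1L]]))
        gr <- GRanges(neg_chrom, IRanges::IRanges(start, width = neg_w),
                      seqinfo = genome)
        names(gr) <- sprintf("%s_neg%d", neg_parent,
                             rep(seq_len(ratio), times = n_pos))
        gr
    })
}
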