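# Independent brute-force oracles and small fixture generators.  The
# oracles deliberately avoid the package's own code paths (and the
# interval machinery of GenomicRanges) so that agreement is evidence, not
# tautology.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
    library(GenomeInfoDb)
})

ALGORITHMS <- c("random_forest", "linear_svm", "adaboost", "gaussian_nb",
                "decision_tree", "knn")

# random regions on a toy genome, as a plain data.frame (1-based closed)
randomRegionsDf <- function(n, chroms = c("chr1", "chr2"),
                            chrom_len = 100000L, max_w = 500L) {
    w <- sample.int(max_w, n, replace = TRUE)
    s <- sample.int(chrom_len - max_w, n, replace = TRUE)
    data.frame(chrom = sample(chroms, n, replace = TRUE),
               start = s, end = s + w - 1L)
}

dfToGRanges <- function(df) {
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start, df$end))
    if (!is.null(df$name)) names(gr) <- df$name
    gr
}

# all-pairs overlap oracle on plain vectors: shared bases of [s1,e1] and
# [s2,e2] on the same chromosome, 1-based closed coordinates
bruteOverlap <- function(qdf, pdf, minbp = 1L) {
    vapply(seq_len(nrow(qdf)), function(i) {
        hit <- FALSE
        for (j in seq_len(nrow(pdf))) {
            if (qdf$chrom[i] != pdf$chrom[j]) next
            shared <- min(qdf$end[i], pdf$end[j]) -
                max(qdf$start[i], pdf$start[j]) + 1L
            if (shared >= minbp) { hit <- TRUE; break }
        }
        hit
    }, logical(1))
}

# pairwise AUC oracle: mean over all (positive, negative) pairs of
# [score_pos > score_neg] + 0.5 * [tie]
bruteAUC <- function(scores, labels) {
    sp <- scores[labels == 1]
    sn <- scores[labels == 0]
    tot <- 0
    for (p in sp) for (q in sn)
        tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(sp) * length(sn))
}

# exhaustive Fisher oracle from binomial coefficients (no dhyper): point
# probability of table (x, r1-x, c1-x, ...) given margins, two-sided
# small-p-values rule
bruteFisher <- function(a, b, cc, d) {
    r1 <- a + b; r2 <- cc + d; c1 <- a + cc; N <- r1 + r2
    if (r1 == 0 || r2 == 0 || c1 == 0 || (N - c1) == 0) return(1)
    support <- max(0, c1 - r2):min(r1, c1)
    probs <- vapply(support, function(x)
        exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(N, c1)),
        numeric(1))
    p_obs <- probs[support == a]
    min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# a small but complete synthetic study for orchestration tests
smallStudyConfig <- function(seed = 11L) {
    simulationConfig(n_chroms = 2L, chrom_length = 4e6,
                     n_target_enhancers = 120L, n_other_enhancers = 120L,
                     seed = seed)
}
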