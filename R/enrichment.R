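#' Contingency table of peak overlap in positives vs negatives
#'
#' Builds the 2x2 table of the enrichment analysis: `a` positives
#' overlapping the peak set, `b` positives not overlapping, `c` negatives
#' overlapping, `d` negatives not overlapping (overlap = >= `minbp` shared
#' bases).
#'
#' @param positives,negatives non-empty GRanges.
#' @param peaks GRanges of the dataset's peaks (may be empty).
#' @param minbp minimum shared bases (default 1).
#' @return named integer vector `c(a=, b=, c=, d=)` with
#'   `a + b = length(positives)` and `c + d = length(negatives)`.
#' @seealso [fisherTwoSided()], [enrichAll()]
#' @export
makeContingencyTable <- function(positives, negatives, peaks, minbp = 1L) {
    if (!length(positives) || !length(negatives))
        stop("positives and negatives must both be non-empty")
    a <- sum(hasOverlap(positives, peaks, minbp = minbp))
    cc <- sum(hasOverlap(negatives, peaks, minbp = minbp))
    c(a = a, b = length(positives) - a,
      c = cc, d = length(negatives) - cc)
}

#' Two-sided Fisher's exact test and sample odds ratio for a 2x2 table
#'
#' The p-value follows the small-p-values convention: the sum of
#' hypergeometric point probabilities, over all tables with the observed
#' margins, that do not exceed the observed table's probability (evaluated
#' in log space for numerical safety, with the customary 1 + 1e-7 relative
#' slack when comparing probabilities).  The odds ratio is the sample
#' estimate `(a*d)/(b*c)` — not the conditional MLE — reported as `Inf`
#' when `b*c = 0` and `a*d > 0`, and 1 when both products are 0.  When any
#' margin is zero the table carries no information and p = 1.
#'
#' @param table named vector `c(a=, b=, c=, d=)` as from
#'   [makeContingencyTable()], or a 2x2 matrix `rbind(c(a, b), c(c, d))`.
#' @return list with elements `odds_ratio` and `p`.
#' @examples
#' fisherTwoSided(c(a = 1, b = 9, c = 1, d = 9))   # OR 1, p 1
#' fisherTwoSided(c(a = 10, b = 0, c = 0, d = 100))
#' @export
fisherTwoSided <- function(table) {
    if (is.matrix(table)) table <- c(a = table[1, 1], b = table[1, 2],
                                     c = table[2, 1], d = table[2, 2])
    a <- table[["a"]]; b <- table[["b"]]
    cc <- table[["c"]]; d <- table[["d"]]
    if (any(c(a, b, cc, d) < 0)) stop("cell counts must be non-negative")
    ad <- a * d; bc <- b * cc
    or <- if (ad == 0 && bc == 0) 1
          else if (bc == 0) Inf
          else ad / bc
    r1 <- a + b; r2 <- cc + d; c1 <- a + cc; c2 <- b + d
    if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0)
        return(list(odds_ratio = or, p = 1))
    support <- max(0, c1 - r2):min(r1, c1)
    logp <- stats::dhyper(support, r1, r2, c1, log = TRUE)
    log_obs <- stats::dhyper(a, r1, r2, c1, log = TRUE)
    p <- sum(exp(logp[logp <= log_obs + log(1 + 1e-7)]))
    list(odds_ratio = or, p = min(p, 1))
}

#' Per-dataset enrichment of peak overlap in positives vs negatives
#'
#' For every dataset in the manifest (manifest order), builds the
#' contingency table of overlap in positives vs negatives and computes the
#' sample odds ratio and two-sided Fisher exact p-value; optionally adds
#' Benjamini-Hochberg adjusted p-values across datasets (off by default —
#' raw p-values are the primary report).
#'
#' @inheritParams buildFeatureMatrix
#' @param adjust logical; add a BH-adjusted p-value column (default
#'   `FALSE`).
#' @return `data.frame` with columns `dataset_id`, `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `p` and (when `adjust`) `p_adjusted`.
#' @export
enrichAll <- function(positives, negatives, peakSets, manifest,
                      minbp = 1L, adjust = FALSE) {
    manifest <- as.data.frame(manifest)
    if (!nrow(manifest)) stop("manifest must contain at least one dataset")
    res <- lapply(manifest$dataset_id, function(id) {
        tab <- makeContingencyTable(positives, negatives, peakSets[[id]],
                                    minbp = minbp)
        ft <- fisherTwoSided(tab)
        data.frame(dataset_id = id, a = tab[["a"]], b = tab[["b"]],
                   c = tab[["c"]], d = tab[["d"]],
                   odds_ratio = ft$odds_ratio, p = ft$p)
    })
    out <- do.call(rbind, res)
    if (adjust) out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
    rownames(out) <- NULL
    out
}

#' Write an enrichment table as TSV
#'
#' Infinite odds ratios are written as the literal `inf`.
#'
#' @param enrichment a `data.frame` from [enrichAll()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeEnrichmentTsv <- function(enrichment, path) {
    out <- enrichment
    out$odds_ratio <- ifelse(is.infinite(out$odds_ratio), "inf",
                             format(out$odds_ratio, digits = 10,
                                    trim = TRUE))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
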