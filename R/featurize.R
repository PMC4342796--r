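#' Build the labeled binary feature matrix from region and peak sets
#'
#' Constructs the classifier input: for every region (positives first, then
#' negatives) and every peak dataset in manifest order, cell (r, c) is 1
#' exactly when region r overlaps dataset c's peaks by at least `minbp`
#' bases.  Positives are labeled 1 and negatives 0.  Features are binary
#' presence/absence — no coverage fractions or signal values.
#'
#' @param positives,negatives GRanges of positive and negative regions.
#' @param peakSets named list (or SimpleList) of GRanges, one per dataset.
#' @param manifest data.frame/DataFrame with columns `dataset_id`, `tissue`,
#'   `stage_coord`, `species`, `mark`; column order of the result follows
#'   manifest row order.  Every `dataset_id` must be present in `peakSets`.
#' @param minbp minimum shared bases for an overlap (default 1).
#' @return an [EnhancerFeatureSet-class].
#' @examples
#' pos <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
#' neg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5001, 5100))
#' pk <- list(d1 = pos)
#' man <- data.frame(dataset_id = "d1", tissue = "heart", stage_coord = 0,
#'                   species = "mouse", mark = "H3K27ac")
#' efs <- buildFeatureMatrix(pos, neg, pk, man)
#' featureMatrix(efs)
#' @seealso [selectFeatures()], [crossValidate()]
#' @export
buildFeatureMatrix <- function(positives, negatives, peakSets, manifest,
                               minbp = 1L) {
    manifest <- as.data.frame(manifest)
    req <- c("dataset_id", "tissue", "stage_coord", "species", "mark")
    miss <- setdiff(req, colnames(manifest))
    if (length(miss))
        stop(sprintf("manifest lacks column(s): %s",
                     paste(miss, collapse = ", ")))
    missing_sets <- setdiff(manifest$dataset_id, names(peakSets))
    if (length(missing_sets))
        stop(sprintf("no peak set supplied for dataset(s): %s",
                     paste(missing_sets, collapse = ", ")))
    regions <- c(GenomicRanges::granges(positives),
                 GenomicRanges::granges(negatives))
    labels <- c(rep(1L, length(positives)), rep(0L, length(negatives)))
    nm_p <- names(positives)
    if (is.null(nm_p)) nm_p <- sprintf("pos%d", seq_along(positives))
    nm_n <- names(negatives)
    if (is.null(nm_n)) nm_n <- sprintf("neg%d", seq_along(negatives))
    names(regions) <- make.unique(c(nm_p, nm_n))
    feats <- vapply(manifest$dataset_id, function(id)
        as.integer(hasOverlap(regions, peakSets[[id]], minbp = minbp)),
        integer(length(regions)))
    if (length(regions) == 1L) feats <- matrix(feats, nrow = 1L)
    dimnames(feats) <- list(names(regions), manifest$dataset_id)
    se <- SummarizedExperiment(
        assays = list(overlap = feats),
        rowRanges = regions,
        colData = DataFrame(manifest[, req], row.names = manifest$dataset_id))
    SummarizedExperiment::rowData(se)$label <- labels
    new("EnhancerFeatureSet", se)
}

#' Restrict a feature set to datasets whose context matches a predicate
#'
#' Keeps only the feature columns whose context metadata satisfy
#' `predicate`; rows and labels are unchanged.  This is how the analysis
#' scenarios choose their feature space (e.g. heart-lineage contexts only,
#' or non-target tissues only).
#'
#' @param x an [EnhancerFeatureSet-class].
#' @param predicate a function taking the `colData` metadata as a
#'   `data.frame` and returning a logical vector over datasets, e.g.
#'   `function(m) m$tissue == "heart"`.
#' @return an [EnhancerFeatureSet-class] with the matching columns.
#' @export
selectFeatures <- function(x, predicate) {
    meta <- as.data.frame(contextMeta(x))
    keep <- predicate(meta)
    if (!is.logical(keep) || length(keep) != nrow(meta))
        stop("predicate must return one logical per dataset")
    keep[is.na(keep)] <- FALSE
    if (!any(keep))
        stop("feature selection matched no dataset")
    x[, keep]
}

#' Write a labeled feature matrix as TSV
#'
#' Emits a tab-separated table with columns `region_id`, `label`, then one
#' 0/1 column per dataset, for inspection or reuse outside R.
#'
#' @param x an [EnhancerFeatureSet-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFeatureMatrixTsv <- function(x, path) {
    tab <- data.frame(region_id = rownames(x),
                      label = regionLabels(x),
                      featureMatrix(x), check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname crossmark-accessors
#' @export
setMethod("featureMatrix", "EnhancerFeatureSet", function(x)
    SummarizedExperiment::assay(x, "overlap"))

#' @rdname crossmark-accessors
#' @export
setMethod("regionLabels", "EnhancerFeatureSet", function(x)
    SummarizedExperiment::rowData(x)$label)

#' @rdname crossmark-accessors
#' @export
setMethod("contextMeta", "EnhancerFeatureSet", function(x)
    SummarizedExperiment::colData(x))

#' @rdname crossmark-accessors
#' @export
setMethod("datasetIds", "EnhancerFeatureSet", function(x) colnames(x))
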