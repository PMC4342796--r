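#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom GenomicRanges GRanges GRangesList
#' @importFrom GenomeInfoDb Seqinfo seqnames seqlengths seqinfo
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges colData
NULL

#' Classifier specification with fixed hyperparameters
#'
#' Describes one of the six supervised classification algorithms of the
#' evaluation suite together with its hyperparameters.  Each algorithm has a
#' fixed default configuration (the configuration the analysis is defined
#' with); constructing a spec with other values requires `override = TRUE` in
#' [classifierSpec()], so that deviations are always explicit.
#'
#' @slot algorithm character(1), one of `"random_forest"`, `"linear_svm"`,
#'   `"adaboost"`, `"gaussian_nb"`, `"decision_tree"`, `"knn"`.
#' @slot hyperparams named list of hyperparameter values.
#' @seealso [classifierSpec()], [trainScore()], [crossValidate()]
#' @exportClass ClassifierSpec
setClass("ClassifierSpec",
    representation(algorithm = "character", hyperparams = "list"))

setValidity("ClassifierSpec", function(object) {
    if (length(object@algorithm) != 1L ||
        !object@algorithm %in% CLASSIFIER_ALGORITHMS)
        return(sprintf("algorithm must be one of: %s",
                       paste(CLASSIFIER_ALGORITHMS, collapse = ", ")))
    if (is.null(names(object@hyperparams)) &&
        length(object@hyperparams) > 0L)
        return("hyperparams must be a named list")
    TRUE
})

#' Labeled binary feature matrix of region-by-dataset peak overlaps
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] specialization holding
#' the classifier input: one row per genomic region (positives then
#' negatives), one column per peak dataset, and a single `"overlap"` assay of
#' 0/1 indicators (1 when the region overlaps that dataset's peaks by at
#' least the overlap threshold).  Row labels (1 = positive class) live in
#' `rowData(x)$label`; per-dataset context metadata (tissue, developmental
#' stage coordinate, species, mark) live in `colData(x)`.
#'
#' Column subsetting (directly or via [selectFeatures()]) restricts the
#' feature space while keeping rows and labels intact.
#'
#' @seealso [buildFeatureMatrix()], [selectFeatures()], [featureMatrix()],
#'   [regionLabels()]
#' @exportClass EnhancerFeatureSet
setClass("EnhancerFeatureSet",
    contains = "RangedSummarizedExperiment")

setValidity("EnhancerFeatureSet", function(object) {
    if (!"overlap" %in% SummarizedExperiment::assayNames(object))
        return("assay 'overlap' is required")
    m <- SummarizedExperiment::assay(object, "overlap")
    if (!all(m %in% c(0L, 1L)))
        return("overlap assay must be binary (0/1)")
    lab <- SummarizedExperiment::rowData(object)$label
    if (is.null(lab))
        return("rowData must contain a 'label' column")
    if (!all(lab %in% c(0L, 1L)))
        return("labels must be 0/1")
    req <- c("dataset_id", "tissue", "stage_coord", "species", "mark")
    miss <- setdiff(req, colnames(SummarizedExperiment::colData(object)))
    if (length(miss))
        return(sprintf("colData lacks column(s): %s",
                       paste(miss, collapse = ", ")))
    TRUE
})

#' Cross-validation report: fold ROC curves, AUCs and feature importances
#'
#' The result of [crossValidate()]: per-fold ROC curves computed on held-out
#' rows only, their AUCs, the arithmetic mean AUC, a vertically averaged ROC
#' curve on a fixed 101-point false-positive-rate grid, and (optionally) a
#' normalized Gini feature-importance table from a full-data fit.
#'
#' @slot foldCurves list of per-fold ROC curves (each a `data.frame` with
#'   columns `fpr`, `tpr`, produced by [rocCurve()]).
#' @slot foldAUC numeric vector of per-fold AUCs.
#' @slot meanAUC numeric(1), arithmetic mean of `foldAUC`.
#' @slot averagedCurve `data.frame` with columns `fpr` (the fixed grid) and
#'   `tpr` (mean held-out TPR at each grid FPR).
#' @slot importances named numeric of normalized importances summing to 1,
#'   or empty when not requested / not a tree-based classifier.
#' @seealso [crossValidate()], [meanAUC()], [foldAUC()], [importanceTable()]
#' @exportClass CVReport
setClass("CVReport",
    representation(foldCurves = "list", foldAUC = "numeric",
                   meanAUC = "numeric", averagedCurve = "data.frame",
                   importances = "numeric"))

setValidity("CVReport", function(object) {
    if (length(object@foldAUC) != length(object@foldCurves))
        return("one AUC per fold curve required")
    if (length(object@meanAUC) != 1L ||
        object@meanAUC < 0 || object@meanAUC > 1)
        return("meanAUC must be a single value in [0, 1]")
    if (length(object@importances) &&
        abs(sum(object@importances) - 1) > 1e-9)
        return("importances must sum to 1")
    TRUE
})

#' Synthetic cross-context epigenome study
#'
#' A complete simulated study: a genome, a target-context true enhancer set,
#' other-tissue enhancer sets, per-context histone-mark peak sets across a
#' developmental lineage and a tissue panel, the dataset manifest describing
#' each peak set's context, and the generating configuration.
#'
#' @slot genome a [GenomeInfoDb::Seqinfo] with chromosome lengths.
#' @slot targetEnhancers GRanges of target-context true enhancers.
#' @slot otherEnhancers GRanges of other-tissue enhancers; `mcols()$tissue`
#'   carries the active tissue and `mcols()$ubiquitous` flags elements marked
#'   in every context.
#' @slot peakSets named [S4Vectors::SimpleList] of GRanges, one per dataset.
#' @slot manifest [S4Vectors::DataFrame] with columns `dataset_id`, `tissue`,
#'   `stage_coord`, `species`, `mark`.
#' @slot config named list, the [simulationConfig()] used.
#' @seealso [simulateStudy()], [exportStudy()], [importStudy()]
#' @exportClass SyntheticStudy
setClass("SyntheticStudy",
    representation(genome = "Seqinfo", targetEnhancers = "GRanges",
                   otherEnhancers = "GRanges", peakSets = "SimpleList",
                   manifest = "DataFrame", config = "list"))

setValidity("SyntheticStudy", function(object) {
    ids <- object@manifest$dataset_id
    if (anyDuplicated(ids))
        return("manifest dataset_id values must be unique")
    if (!setequal(ids, names(object@peakSets)))
        return("peakSets names must match manifest dataset_id")
    within_bounds <- function(gr) {
        if (!length(gr)) return(TRUE)
        len <- seqlengths(object@genome)[as.character(seqnames(gr))]
        all(GenomicRanges::start(gr) >= 1 & GenomicRanges::end(gr) <= len)
    }
    if (!within_bounds(object@targetEnhancers) ||
        !within_bounds(object@otherEnhancers))
        return("enhancers must lie within genome bounds")
    for (gr in as.list(object@peakSets))
        if (!within_bounds(gr)) return("peaks must lie within genome bounds")
    hits <- GenomicRanges::countOverlaps(object@targetEnhancers,
                                         object@otherEnhancers)
    if (any(hits > 0))
        return("target and other enhancers must not overlap")
    TRUE
})
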