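#' Accessors for crossmark result objects
#'
#' Small accessor generics for the package's S4 classes: the binary feature
#' matrix, the 0/1 region labels and per-dataset context metadata of an
#' [EnhancerFeatureSet-class]; the fold AUCs, mean AUC and importance table
#' of a [CVReport-class]; and the components of a [SyntheticStudy-class].
#'
#' @param x an object of the documented class.
#' @return `featureMatrix`: integer 0/1 matrix, regions by datasets.
#'   `regionLabels`: integer vector of 0/1 labels. `contextMeta`: a
#'   `DataFrame` of per-dataset context metadata. `datasetIds`: character
#'   vector of dataset identifiers. `foldAUC`/`meanAUC`: numeric.
#'   `importanceTable`: named numeric summing to 1 (or empty).
#'   `peakSets`/`targetEnhancers`/`otherEnhancers`/`studyGenome`/
#'   `studyManifest`: the corresponding study component.
#' @name crossmark-accessors
NULL

#' @rdname crossmark-accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname crossmark-accessors
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' @rdname crossmark-accessors
#' @export
setGeneric("contextMeta", function(x) standardGeneric("contextMeta"))

#' @rdname crossmark-accessors
#' @export
setGeneric("datasetIds", function(x) standardGeneric("datasetIds"))

#' @rdname crossmark-accessors
#' @export
setGeneric("foldAUC", function(x) standardGeneric("foldAUC"))

#' @rdname crossmark-accessors
#' @export
setGeneric("meanAUC", function(x) standardGeneric("meanAUC"))

#' @rdname crossmark-accessors
#' @export
setGeneric("importanceTable", function(x) standardGeneric("importanceTable"))

#' @rdname crossmark-accessors
#' @export
setGeneric("peakSets", function(x) standardGeneric("peakSets"))

#' @rdname crossmark-accessors
#' @export
setGeneric("targetEnhancers", function(x) standardGeneric("targetEnhancers"))

#' @rdname crossmark-accessors
#' @export
setGeneric("otherEnhancers", function(x) standardGeneric("otherEnhancers"))

#' @rdname crossmark-accessors
#' @export
setGeneric("studyGenome", function(x) standardGeneric("studyGenome"))

#' @rdname crossmark-accessors
#' @export
setGeneric("studyManifest", function(x) standardGeneric("studyManifest"))
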