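#' Built-in feature predicates for the analysis scenarios
#'
#' Helpers producing the column predicates used by the three scenarios:
#' lineage ("stage") contexts of the target tissue, non-target tissue
#' contexts, or a single mark.
#'
#' @param tissue tissue name.
#' @param mark mark name.
#' @return a predicate function over the context-metadata data.frame,
#'   suitable for [selectFeatures()] and [runScenario()].
#' @export
featuresTissue <- function(tissue) {
    force(tissue)
    function(m) m$tissue == tissue
}

#' @rdname featuresTissue
#' @export
featuresNotTissue <- function(tissue) {
    force(tissue)
    function(m) m$tissue != tissue
}

#' @rdname featuresTissue
#' @export
featuresMark <- function(mark) {
    force(mark)
    function(m) m$mark == mark
}

#' Run one enhancer-prediction scenario on a study
#'
#' The scenario machinery of the analysis: positives are the target
#' context's enhancers (or a supplied set, e.g. the cross-species degraded
#' copy); negatives are either `ratio` chromosome/length-matched random
#' background regions per positive (excluding all known enhancers) or the
#' other-tissue enhancer regions themselves; features are the peak-overlap
#' columns whose context metadata satisfy `featurePredicate`; evaluation is
#' stratified five-fold cross-validation of the given classifier, with
#' normalized Gini importances attached for tree-based classifiers.
#'
#' One matched-negative draw is made per scenario and shared across folds
#' (and, in [runClassifierSweep()], across algorithms), keeping comparisons
#' paired.  All seeds derive deterministically from `masterSeed` and the
#' scenario `name`, so re-ordering scenarios cannot change results.
#'
#' @param study a [SyntheticStudy-class].
#' @param featurePredicate predicate over the context metadata (see
#'   [selectFeatures()] and [featuresTissue()]).
#' @param negativeMode `"genomic_background"` or `"other_enhancers"`.
#' @param spec a [ClassifierSpec-class] (default random forest).
#' @param positives optional GRanges overriding the positive set.
#' @param nFolds cross-validation folds (default 5).
#' @param ratio matched negatives per positive (default 10).
#' @param masterSeed integer master seed.
#' @param name scenario name used for seed derivation.
#' @return a [CVReport-class].
#' @export
runScenario <- function(study, featurePredicate,
                        negativeMode = c("genomic_background",
                                         "other_enhancers"),
                        spec = classifierSpec("random_forest"),
                        positives = NULL, nFolds = 5L, ratio = 10L,
                        masterSeed = 1L, name = "scenario") {
    negativeMode <- match.arg(negativeMode)
    if (is.null(positives)) positives <- targetEnhancers(study)
    negatives <- scenarioNegatives(study, positives, negativeMode, ratio,
                                   deriveSeed(masterSeed,
                                              paste0(name, "/negatives")))
    efs <- buildFeatureMatrix(positives, negatives, peakSets(study),
                              studyManifest(study))
    efs <- selectFeatures(efs, featurePredicate)
    crossValidate(spec, efs, nFolds = nFolds,
                  seed = deriveSeed(masterSeed, paste0(name, "/cv")),
                  importance = TRUE)
}

scenarioNegatives <- function(study, positives, negativeMode, ratio, seed) {
    if (negativeMode == "other_enhancers")
        return(GenomicRanges::granges(otherEnhancers(study),
                                      use.names = TRUE))
    exclusions <- c(GenomicRanges::granges(positives),
                    GenomicRanges::granges(targetEnhancers(study)),
                    GenomicRanges::granges(otherEnhancers(study)))
    sampleMatchedNegatives(positives, studyGenome(study),
                           exclusions = exclusions, ratio = ratio,
                           seed = seed)
}

#' Compare the six classification algorithms on one scenario
#'
#' Runs every algorithm of the suite on identical folds and identical
#' matched negatives (the fold assignment depends only on the labels and
#' the derived seed, so it is shared), returning the mean cross-validated
#' AUC per algorithm.
#'
#' @inheritParams runScenario
#' @return `data.frame` with columns `algorithm` and `mean_auc`.
#' @export
runClassifierSweep <- function(study, featurePredicate,
                               negativeMode = "genomic_background",
                               positives = NULL, nFolds = 5L, ratio = 10L,
                               masterSeed = 1L, name = "sweep") {
    if (is.null(positives)) positives <- targetEnhancers(study)
    negatives <- scenarioNegatives(study, positives, negativeMode, ratio,
                                   deriveSeed(masterSeed,
                                              paste0(name, "/negatives")))
    efs <- buildFeatureMatrix(positives, negatives, peakSets(study),
                              studyManifest(study))
    efs <- selectFeatures(efs, featurePredicate)
    cv_seed <- deriveSeed(masterSeed, paste0(name, "/cv"))
    auc <- vapply(CLASSIFIER_ALGORITHMS, function(alg)
        meanAUC(crossValidate(classifierSpec(alg), efs, nFolds = nFolds,
                              seed = cv_seed)), numeric(1))
    data.frame(algorithm = CLASSIFIER_ALGORITHMS, mean_auc = unname(auc))
}

#' Leave-one-context-out prediction of histone-mark locations
#'
#' For each lineage (target-tissue) dataset in turn, treats that dataset's
#' peak regions as positives, samples `ratio` matched background negatives
#' per positive, featurizes both against all *other* datasets' peaks, and
#' cross-validates the classifier — measuring how well a context's marks
#' can be imputed from the remaining contexts.
#'
#' @inheritParams runScenario
#' @param spec classifier (default random forest).
#' @return `data.frame` with columns `dataset_id`, `tissue`, `stage_coord`,
#'   `mark`, `mean_auc`.
#' @export
runMarkLeaveout <- function(study, spec = classifierSpec("random_forest"),
                            nFolds = 5L, ratio = 10L, masterSeed = 1L) {
    man <- as.data.frame(studyManifest(study))
    heart <- man[man$tissue == "heart", ]
    if (nrow(heart) < 1L || nrow(man) < 2L)
        stop("mark leave-out needs at least two contexts")
    res <- lapply(seq_len(nrow(heart)), function(i) {
        id <- heart$dataset_id[i]
        positives <- peakSets(study)[[id]]
        neg_seed <- deriveSeed(masterSeed, paste0("leaveout/", id, "/neg"))
        negatives <- sampleMatchedNegatives(
            positives, studyGenome(study),
            exclusions = GenomicRanges::granges(positives),
            ratio = ratio, seed = neg_seed)
        keep <- man$dataset_id != id
        efs <- buildFeatureMatrix(positives, negatives,
                                  peakSets(study)[keep],
                                  man[keep, ])
        rep <- crossValidate(spec, efs, nFolds = nFolds,
                             seed = deriveSeed(masterSeed,
                                               paste0("leaveout/", id)))
        data.frame(dataset_id = id, tissue = heart$tissue[i],
                   stage_coord = heart$stage_coord[i], mark = heart$mark[i],
                   mean_auc = meanAUC(rep))
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

#' Run the full analysis grid on a study
#'
#' Orchestrates the complete evaluation: the three scenarios (lineage
#' stages, non-target tissues, cross-species degraded positives) each
#' against genomic-background and other-enhancer negatives with a random
#' forest; the six-algorithm sweep on the lineage features; per-dataset
#' enrichment (odds ratio, Fisher exact p) of lineage marks in target
#' enhancers vs matched background; and the leave-one-context-out mark
#' prediction table.  Every random draw derives from `masterSeed`, so the
#' report is bit-for-bit reproducible.
#'
#' @param study a [SyntheticStudy-class].
#' @param masterSeed integer master seed.
#' @param nFolds cross-validation folds (default 5).
#' @param ratio matched negatives per positive (default 10).
#' @return named list with elements `scenarios` (list of
#'   [CVReport-class]), `sweep`, `enrichment`, `mark_leaveout`
#'   (data.frames) and `provenance`.
#' @seealso [writeReportJson()]
#' @export
runStudyReport <- function(study, masterSeed = 1L, nFolds = 5L,
                           ratio = 10L) {
    cfg <- study@config
    heart_pred <- featuresTissue("heart")
    tissue_pred <- featuresNotTissue("heart")
    xspec_pos <- degradeCrossSpecies(
        targetEnhancers(study),
        unmappable_frac = cfg$unmappable_frac,
        map_jitter_sd = cfg$map_jitter_sd, genome = studyGenome(study),
        seed = deriveSeed(masterSeed, "cross_species/map"))
    grid <- list(
        stage_background = list(pred = heart_pred,
                                neg = "genomic_background", pos = NULL),
        stage_other = list(pred = heart_pred, neg = "other_enhancers",
                           pos = NULL),
        tissue_background = list(pred = tissue_pred,
                                 neg = "genomic_background", pos = NULL),
        tissue_other = list(pred = tissue_pred, neg = "other_enhancers",
                            pos = NULL),
        species_background = list(pred = heart_pred,
                                  neg = "genomic_background",
                                  pos = xspec_pos),
        species_other = list(pred = heart_pred, neg = "other_enhancers",
                             pos = xspec_pos))
    scenarios <- lapply(names(grid), function(nm) {
        g <- grid[[nm]]
        runScenario(study, g$pred, g$neg, positives = g$pos,
                    nFolds = nFolds, ratio = ratio,
                    masterSeed = masterSeed, name = nm)
    })
    names(scenarios) <- names(grid)

    sweep <- rbind(
        cbind(negative_mode = "genomic_background",
              runClassifierSweep(study, heart_pred, "genomic_background",
                                 nFolds = nFolds, ratio = ratio,
                                 masterSeed = masterSeed,
                                 name = "sweep_bg")),
        cbind(negative_mode = "other_enhancers",
              runClassifierSweep(study, heart_pred, "other_enhancers",
                                 nFolds = nFolds, ratio = ratio,
                                 masterSeed = masterSeed,
                                 name = "sweep_other")))

    enr_neg <- scenarioNegatives(study, targetEnhancers(study),
                                 "genomic_background", ratio,
                                 deriveSeed(masterSeed, "enrich/negatives"))
    man <- as.data.frame(studyManifest(study))
    heart_man <- man[man$tissue == "heart", ]
    enrichment <- enrichAll(targetEnhancers(study), enr_neg,
                            peakSets(study), heart_man)

    leaveout <- runMarkLeaveout(study, nFolds = nFolds, ratio = ratio,
                                masterSeed = masterSeed)

    list(scenarios = scenarios, sweep = sweep, enrichment = enrichment,
         mark_leaveout = leaveout,
         provenance = list(master_seed = masterSeed, n_folds = nFolds,
                           ratio = ratio, config = cfg))
}

#' Serialize a study report as canonical JSON
#'
#' Writes the full report (fold AUCs, mean AUCs, averaged ROC grids,
#' importances, sweep / enrichment / leave-out tables, provenance) with
#' full numeric precision; identical inputs and master seed produce
#' byte-identical files.
#'
#' @param report list from [runStudyReport()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeReportJson <- function(report, path) {
    as_plain <- function(x) {
        if (is(x, "CVReport"))
            list(fold_auc = x@foldAUC, mean_auc = x@meanAUC,
                 averaged_curve = x@averagedCurve,
                 importances = as.list(x@importances))
        else if (is.list(x) && !is.data.frame(x)) lapply(x, as_plain)
        else x
    }
    jsonlite::write_json(as_plain(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(path)
}
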