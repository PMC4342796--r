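#' Stratified cross-validation folds
#'
#' Partitions row indices into `nFolds` test folds preserving the class
#' ratio: within each class, indices are shuffled and dealt round-robin, so
#' per-fold class counts differ by at most one from exact stratification.
#' Every index is tested exactly once.  With the 1-positive :
#' 10-matched-negative design this guarantees each fold keeps its share of
#' positives, which unstratified folding can lose entirely.
#'
#' @param labels 0/1 vector; both classes must be present.  When a class
#'   has fewer members than folds, some test folds receive none of it (the
#'   partition is still valid); [crossValidate()] additionally requires
#'   `nFolds` not to exceed the minority-class count so every training
#'   split keeps both classes.
#' @param nFolds number of folds (default 5).
#' @param seed integer seed; folds are deterministic given labels and seed.
#' @return list of length `nFolds`; each element is
#'   `list(train = <indices>, test = <indices>)`.
#' @export
stratifiedFolds <- function(labels, nFolds = 5L, seed = 1L) {
    labels <- as.integer(labels)
    counts <- table(factor(labels, levels = c(0L, 1L)))
    if (any(counts == 0L))
        stop("both classes must be present to form folds")
    if (nFolds < 2L || nFolds > length(labels))
        stop("nFolds must be between 2 and the number of rows")
    assign_fold <- integer(length(labels))
    withSeed(seed, {
        # deal each class round-robin, rotating the starting fold between
        # classes so that total fold sizes stay balanced too
        offset <- 0L
        for (cl in c(0L, 1L)) {
            idx <- which(labels == cl)
            idx <- idx[order(stats::runif(length(idx)))]
            assign_fold[idx] <-
                ((seq_along(idx) - 1L + offset) %% nFolds) + 1L
            offset <- (offset + length(idx)) %% nFolds
        }
    })
    lapply(seq_len(nFolds), function(f)
        list(train = which(assign_fold != f), test = which(assign_fold == f)))
}

#' ROC curve and AUC from scores
#'
#' Sweeps thresholds over the unique scores to build the stepped ROC curve
#' (starting at (0,0), ending at (1,1)) and computes the AUC with the
#' Mann-Whitney rank statistic using midranks for ties, which equals the
#' trapezoidal area under the stepped curve.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels 0/1 labels; both classes must be present.
#' @return a `data.frame` with columns `fpr`, `tpr` (both non-decreasing in
#'   \[0,1\]) and attribute `auc`; retrieve the AUC with `attr(x, "auc")` or
#'   [aucScore()].
#' @examples
#' roc <- rocCurve(c(.9, .8, .2, .1), c(1, 1, 0, 0))
#' attr(roc, "auc")   # 1: perfect separation
#' @export
rocCurve <- function(scores, labels) {
    labels <- as.integer(labels)
    n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
    if (n1 == 0L || n0 == 0L)
        stop("both classes must be present to compute a ROC curve")
    o <- order(scores, decreasing = TRUE)
    s <- scores[o]; y <- labels[o]
    # collapse tied scores into single threshold steps
    last_of_run <- c(s[-1L] != s[-length(s)], TRUE)
    tp <- cumsum(y == 1L)[last_of_run]
    fp <- cumsum(y == 0L)[last_of_run]
    curve <- data.frame(fpr = c(0, fp / n0), tpr = c(0, tp / n1))
    attr(curve, "auc") <- aucScore(scores, labels)
    curve
}

#' @rdname rocCurve
#' @export
aucScore <- function(scores, labels) {
    labels <- as.integer(labels)
    n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
    if (n1 == 0L || n0 == 0L)
        stop("both classes must be present to compute an AUC")
    r <- rank(scores, ties.method = "average")
    (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated evaluation of a classifier on a feature set
#'
#' Runs stratified `nFolds`-fold cross-validation: per fold, the classifier
#' is trained on the training rows and scores the held-out rows only; a ROC
#' curve and AUC are computed per fold.  The summary AUC is the arithmetic
#' mean of the fold AUCs (not a pooled-score AUC), and the displayed curve
#' is the vertical (TPR at fixed FPR) average of the fold curves on a
#' 101-point FPR grid — the AUC is never recomputed from the averaged curve.
#' Optionally attaches a normalized Gini importance table from a full-data
#' fit ([giniImportance()]) for tree-based classifiers.
#'
#' @param spec a [ClassifierSpec-class].
#' @param x an [EnhancerFeatureSet-class] with both classes present.
#' @param nFolds folds (default 5).
#' @param seed integer master seed for fold shuffling and the learners.
#' @param importance logical; compute feature importances (tree-based specs
#'   only; default `FALSE`).
#' @return a [CVReport-class].
#' @export
crossValidate <- function(spec, x, nFolds = 5L, seed = 1L,
                          importance = FALSE) {
    feats <- featureMatrix(x)
    labels <- as.integer(regionLabels(x))
    counts <- table(factor(labels, levels = c(0L, 1L)))
    if (nFolds > min(counts))
        stop("nFolds must not exceed the minority-class count")
    folds <- stratifiedFolds(labels, nFolds = nFolds, seed = seed)
    curves <- vector("list", length(folds))
    aucs <- numeric(length(folds))
    for (f in seq_along(folds)) {
        tr <- folds[[f]]$train; te <- folds[[f]]$test
        sc <- trainScore(spec, feats[tr, , drop = FALSE], labels[tr],
                         feats[te, , drop = FALSE],
                         seed = deriveSeed(seed, sprintf("fold%d", f)))
        curves[[f]] <- rocCurve(sc, labels[te])
        aucs[f] <- attr(curves[[f]], "auc")
    }
    grid <- seq(0, 1, length.out = 101L)
    tpr_grid <- rowMeans(vapply(curves, function(cu)
        stats::approx(cu$fpr, cu$tpr, xout = grid, ties = max,
                      yleft = 0, yright = 1)$y, numeric(length(grid))))
    imp <- numeric(0)
    if (importance && spec@algorithm %in% c("random_forest",
                                            "decision_tree"))
        imp <- giniImportance(spec, x, seed = deriveSeed(seed, "importance"))
    new("CVReport", foldCurves = curves, foldAUC = aucs,
        meanAUC = mean(aucs),
        averagedCurve = data.frame(fpr = grid, tpr = tpr_grid),
        importances = imp)
}

#' Normalized Gini feature importance from a full-data fit
#'
#' Fits the tree-based classifier on the complete feature set and reports,
#' per feature, the total Gini impurity decrease over all splits on that
#' feature (weighted by node sample fraction, summed over trees), normalized
#' to sum to 1.  Only defined for `random_forest` and `decision_tree`
#' specs.  Importance is computed from a single full-data fit, matching how
#' one importance table is reported per prediction task.
#'
#' @param spec a tree-based [ClassifierSpec-class].
#' @param x an [EnhancerFeatureSet-class].
#' @param seed integer seed for the forest's bootstrap / feature
#'   subsampling.
#' @return named numeric vector (names = dataset ids) summing to 1.
#' @export
giniImportance <- function(spec, x, seed = 1L) {
    if (!spec@algorithm %in% c("random_forest", "decision_tree"))
        stop("Gini importance is defined for tree-based classifiers only")
    feats <- featureMatrix(x)
    labels <- as.integer(regionLabels(x))
    hp <- spec@hyperparams
    df <- as.data.frame(feats)
    colnames(df) <- paste0("f", seq_len(ncol(df)))
    single <- spec@algorithm == "decision_tree"
    fit <- ranger::ranger(
        x = df, y = factor(labels, levels = c(0L, 1L)),
        num.trees = if (single) 1L else hp$n_trees,
        mtry = if (single) ncol(df) else max(1L, floor(sqrt(ncol(df)))),
        max.depth = hp$max_depth, splitrule = "gini", probability = TRUE,
        replace = !single, sample.fraction = 1,
        importance = "impurity", num.threads = 1L, seed = as.integer(seed))
    imp <- fit$variable.importance
    total <- sum(imp)
    imp <- if (total > 0) imp / total else rep(1 / length(imp), length(imp))
    names(imp) <- colnames(feats)
    imp
}

#' @rdname crossmark-accessors
#' @export
setMethod("foldAUC", "CVReport", function(x) x@foldAUC)

#' @rdname crossmark-accessors
#' @export
setMethod("meanAUC", "CVReport", function(x) x@meanAUC)

#' @rdname crossmark-accessors
#' @export
setMethod("importanceTable", "CVReport", function(x) x@importances)

setMethod("show", "CVReport", function(object) {
    cat(sprintf("CVReport: %d folds, mean AUC = %.3f (folds: %s)\n",
                length(object@foldAUC), object@meanAUC,
                paste(sprintf("%.3f", object@foldAUC), collapse = ", ")))
    if (length(object@importances)) {
        top <- sort(object@importances, decreasing = TRUE)
        top <- utils::head(top, 5L)
        cat("top importances:",
            paste(sprintf("%s=%.3f", names(top), top), collapse = ", "),
            "\n")
    }
})
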