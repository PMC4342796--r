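toyEFS <- function(features, labels) {
    n <- nrow(features)
    ids <- colnames(features)
    if (is.null(ids)) ids <- paste0("d", seq_len(ncol(features)))
    pos <- which(labels == 1); neg <- which(labels == 0)
    man <- data.frame(dataset_id = ids, tissue = "heart",
                      stage_coord = seq_along(ids), species = "mouse",
                      mark = "H3K27ac")
    # build via the constructor path: regions at distinct loci, peak sets
    # materialized from the requested feature pattern
    regions <- GRanges("chr1", IRanges(seq_len(n) * 1000L, width = 100L))
    pks <- lapply(seq_along(ids), function(j)
        regions[features[, j] == 1])
    efs <- buildFeatureMatrix(regions[c(pos, neg)], GRanges(),
                              setNames(pks, ids), man)
    # re-impose requested labels/ordering (positives listed first above)
    o <- c(pos, neg)
    SummarizedExperiment::rowData(efs)$label <- labels[o]
    efs
}

test_that("stratified folds partition indices with balanced class counts", {
    labels <- c(rep(1, 10), rep(0, 100))
    folds <- stratifiedFolds(labels, nFolds = 5, seed = 1)
    expect_length(folds, 5L)
    test_idx <- lapply(folds, `[[`, "test")
    expect_setequal(unlist(test_idx), seq_along(labels))
    expect_equal(sum(lengths(test_idx)), length(labels))   # disjoint
    for (f in folds) {
        expect_equal(sum(labels[f$test] == 1), 2)
        expect_equal(sum(labels[f$test] == 0), 20)
        expect_setequal(c(f$train, f$test), seq_along(labels))
    }
})

test_that("fold partition holds for random label vectors", {
    set.seed(41)
    for (i in 1:20) {
        n <- sample(20:200, 1)
        labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
        k <- min(5, table(labels))
        if (k < 2) next
        folds <- stratifiedFolds(labels, nFolds = k, seed = i)
        test_idx <- unlist(lapply(folds, `[[`, "test"))
        expect_equal(sort(test_idx), seq_len(n))
        per_fold_pos <- vapply(folds, function(f)
            sum(labels[f$test] == 1), numeric(1))
        expect_lte(diff(range(per_fold_pos)), 1)
    }
    expect_error(stratifiedFolds(rep(1, 10), 5, 1), "both classes")
    expect_error(stratifiedFolds(c(1, 0), 3, 1), "number of rows")
})

test_that("two-fold split of a two-row set tests each row once", {
    folds <- stratifiedFolds(c(1, 0), nFolds = 2, seed = 1)
    expect_setequal(unlist(lapply(folds, `[[`, "test")), c(1L, 2L))
    expect_true(all(lengths(lapply(folds, `[[`, "test")) == 1L))
})

test_that("ROC endpoints, perfect separation and total ties behave", {
    roc <- rocCurve(c(.9, .8, .2, .1), c(1, 1, 0, 0))
    expect_equal(attr(roc, "auc"), 1)
    expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
    expect_equal(roc$fpr[nrow(roc)], 1)
    expect_equal(roc$tpr[nrow(roc)], 1)
    expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
    expect_equal(aucScore(rep(0.5, 30), rep(c(0, 1), 15)), 0.5)
    expect_error(aucScore(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC equals the pairwise brute-force oracle and trapezoid area", {
    set.seed(42)
    for (i in 1:100) {
        n <- sample(10:50, 1)
        scores <- round(runif(n), sample(1:3, 1))  # force some ties
        labels <- rbinom(n, 1, 0.5)
        if (length(unique(labels)) < 2) next
        auc <- aucScore(scores, labels)
        expect_equal(auc, bruteAUC(scores, labels), tolerance = 1e-12)
        roc <- rocCurve(scores, labels)
        trap <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
        expect_equal(auc, trap, tolerance = 1e-12)
    }
})

test_that("AUC is antisymmetric under score negation and invariant to monotone maps", {
    set.seed(43)
    scores <- runif(60); labels <- rbinom(60, 1, 0.4)
    auc <- aucScore(scores, labels)
    expect_equal(aucScore(-scores, labels), 1 - auc, tolerance = 1e-12)
    mono <- function(x) exp(3 * x) + x
    expect_equal(aucScore(mono(scores), labels), auc, tolerance = 1e-12)
    expect_equal(rocCurve(mono(scores), labels)$tpr,
                 rocCurve(scores, labels)$tpr)
})

test_that("our AUC agrees with an established ROC implementation", {
    skip_if_not_installed("pROC")
    set.seed(44)
    scores <- round(runif(200), 2)
    labels <- rbinom(200, 1, 0.3)
    expect_equal(aucScore(scores, labels),
                 as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                levels = c(0, 1),
                                                direction = "<",
                                                quiet = TRUE))),
                 tolerance = 1e-12)
})

test_that("cross-validation on a label-identical feature gives AUC 1", {
    set.seed(45)
    labels <- rep(c(1, 0), c(30, 60))
    feats <- cbind(d1 = labels, d2 = rbinom(90, 1, 0.5))
    efs <- toyEFS(feats, labels)
    rep <- crossValidate(classifierSpec("random_forest"), efs, seed = 2)
    expect_equal(meanAUC(rep), 1)
    expect_length(foldAUC(rep), 5L)
    expect_equal(nrow(rep@averagedCurve), 101L)
    expect_true(all(diff(rep@averagedCurve$tpr) >= -1e-12))
})

test_that("label-permuted features give chance-level AUC", {
    set.seed(46)
    n <- 600
    feats <- cbind(d1 = rbinom(n, 1, 0.4), d2 = rbinom(n, 1, 0.5),
                   d3 = rbinom(n, 1, 0.6))
    labels <- sample(rep(c(1, 0), c(n / 2, n / 2)))
    efs <- toyEFS(feats, labels)
    rep <- crossValidate(classifierSpec("random_forest"), efs, seed = 0)
    expect_gt(meanAUC(rep), 0.4)
    expect_lt(meanAUC(rep), 0.6)
})

test_that("Gini importances are normalized, dominance-ordered and equivariant", {
    set.seed(47)
    n <- 1000
    informative <- rbinom(n, 1, 0.5)
    labels <- ifelse(informative == 1, rbinom(n, 1, 0.95),
                     rbinom(n, 1, 0.05))
    feats <- cbind(d1 = informative, d2 = rbinom(n, 1, 0.5),
                   d3 = rbinom(n, 1, 0.5), d4 = rbinom(n, 1, 0.5))
    efs <- toyEFS(feats, labels)
    for (alg in c("random_forest", "decision_tree")) {
        imp <- giniImportance(classifierSpec(alg), efs, seed = 0)
        expect_equal(sum(imp), 1, tolerance = 1e-9)
        expect_true(all(imp >= 0))
        expect_gt(imp[["d1"]], 0.8)
    }
    expect_error(giniImportance(classifierSpec("knn"), efs), "tree-based")
    # permutation of feature columns permutes the importance table
    perm <- c(3L, 1L, 4L, 2L)
    efs_perm <- toyEFS(feats[, perm], labels)
    imp <- giniImportance(classifierSpec("decision_tree"), efs, seed = 0)
    imp_perm <- giniImportance(classifierSpec("decision_tree"), efs_perm,
                               seed = 0)
    # equivariant up to split tie-breaking among equally good thresholds,
    # which legitimately depends on column order
    expect_equal(imp_perm[names(imp)], imp, tolerance = 0.01)
})

test_that("importance splits between duplicated informative features", {
    set.seed(48)
    n <- 1000
    informative <- rbinom(n, 1, 0.5)
    labels <- ifelse(informative == 1, rbinom(n, 1, 0.95),
                     rbinom(n, 1, 0.05))
    noise <- cbind(rbinom(n, 1, 0.5), rbinom(n, 1, 0.5))
    single <- toyEFS(cbind(d1 = informative, n1 = noise[, 1],
                           n2 = noise[, 2]), labels)
    dup <- toyEFS(cbind(d1 = informative, d1b = informative,
                        n1 = noise[, 1], n2 = noise[, 2]), labels)
    spec <- classifierSpec("random_forest")
    imp_single <- giniImportance(spec, single, seed = 0)
    imp_dup <- giniImportance(spec, dup, seed = 0)
    expect_equal(imp_dup[["d1"]] + imp_dup[["d1b"]], imp_single[["d1"]],
                 tolerance = 0.1)
})
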