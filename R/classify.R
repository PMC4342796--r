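CLASSIFIER_ALGORITHMS <- c("random_forest", "linear_svm", "adaboost",
                           "gaussian_nb", "decision_tree", "knn")

# Fixed hyperparameter suite of the evaluation framework.
CLASSIFIER_DEFAULTS <- list(
    random_forest = list(n_trees = 10L, max_depth = 5L),
    linear_svm    = list(cost = 0.1),
    adaboost      = list(n_estimators = 50L, learning_rate = 1,
                         base_depth = 1L),
    gaussian_nb   = list(var_smoothing = 1e-9),
    decision_tree = list(max_depth = 5L),
    knn           = list(k = 3L))

#' Construct a classifier specification
#'
#' The evaluation suite runs six fixed-configuration algorithms: random
#' forests (10 trees, maximum depth 5, Gini criterion, per-tree probability
#' averaging), linear SVM (cost 0.1), AdaBoost (50 depth-limited
#' decision-tree learners, learning rate 1; base-learner depth defaults to
#' 1-level stumps), Gaussian naive Bayes (Gaussian class-conditional
#' densities even on binary features, with default variance smoothing),
#' decision tree (maximum depth 5, Gini), and k-nearest neighbours (k = 3,
#' Euclidean distance on the binary features).  These configurations define
#' the analysis; overriding any hyperparameter requires `override = TRUE`.
#'
#' @param algorithm one of `"random_forest"`, `"linear_svm"`, `"adaboost"`,
#'   `"gaussian_nb"`, `"decision_tree"`, `"knn"`.
#' @param ... hyperparameter overrides (rejected unless `override = TRUE`).
#' @param override logical; set `TRUE` to allow non-default hyperparameters.
#' @return a [ClassifierSpec-class].
#' @examples
#' classifierSpec("random_forest")
#' classifierSpec("knn", k = 5, override = TRUE)
#' @export
classifierSpec <- function(algorithm = CLASSIFIER_ALGORITHMS, ...,
                           override = FALSE) {
    algorithm <- match.arg(algorithm)
    hp <- CLASSIFIER_DEFAULTS[[algorithm]]
    extra <- list(...)
    if (length(extra)) {
        if (!override)
            stop("non-default hyperparameters require override = TRUE")
        unknown <- setdiff(names(extra), names(hp))
        if (length(unknown))
            stop(sprintf("unknown hyperparameter(s) for %s: %s", algorithm,
                         paste(unknown, collapse = ", ")))
        hp[names(extra)] <- extra
    }
    new("ClassifierSpec", algorithm = algorithm, hyperparams = hp)
}

setMethod("show", "ClassifierSpec", function(object) {
    hp <- object@hyperparams
    cat(sprintf("ClassifierSpec: %s (%s)\n", object@algorithm,
                paste(names(hp), unlist(hp), sep = "=", collapse = ", ")))
})

#' Train a classifier and score test rows
#'
#' Fits the algorithm described by `spec` on the training rows and returns
#' one real-valued score per test row, higher meaning more confidently
#' positive: the random forest score is the mean class-1 probability over
#' trees; the linear SVM score is the signed decision value; AdaBoost the
#' staged weighted-vote sum; naive Bayes the posterior log-odds; the
#' decision tree its class-1 leaf probability; KNN the fraction of the k
#' nearest training rows labeled 1 (distance ties broken by training-row
#' order).
#'
#' @param spec a [ClassifierSpec-class].
#' @param train numeric feature matrix of training rows (or an
#'   [EnhancerFeatureSet-class], in which case `labels` defaults to its
#'   region labels).
#' @param labels 0/1 training labels; both classes must be present.
#' @param test numeric feature matrix of rows to score (same columns as
#'   `train`).
#' @param seed integer seed for the stochastic learners (forest bootstrap /
#'   feature subsampling, tree tie-breaking).
#' @return numeric vector of scores, one per test row.
#' @export
trainScore <- function(spec, train, labels = NULL, test, seed = 0L) {
    stopifnot(is(spec, "ClassifierSpec"))
    if (is(train, "EnhancerFeatureSet")) {
        if (is.null(labels)) labels <- regionLabels(train)
        train <- featureMatrix(train)
    }
    if (is(test, "EnhancerFeatureSet")) test <- featureMatrix(test)
    train <- as.matrix(train)
    test <- as.matrix(test)
    labels <- as.integer(labels)
    if (length(unique(labels)) < 2L)
        stop("training labels must contain both classes")
    if (ncol(test) != ncol(train))
        stop("train and test must have the same feature columns")
    colnames(train) <- colnames(test) <- paste0("f", seq_len(ncol(train)))
    hp <- spec@hyperparams
    switch(spec@algorithm,
        random_forest = scoreRanger(train, labels, test,
            num_trees = hp$n_trees, max_depth = hp$max_depth,
            mtry = max(1L, floor(sqrt(ncol(train)))), bootstrap = TRUE,
            seed = seed),
        decision_tree = scoreRanger(train, labels, test,
            num_trees = 1L, max_depth = hp$max_depth,
            mtry = ncol(train), bootstrap = FALSE, seed = seed),
        linear_svm = scoreLinearSvm(train, labels, test, cost = hp$cost),
        adaboost = scoreAdaboost(train, labels, test,
            n_estimators = hp$n_estimators,
            learning_rate = hp$learning_rate,
            base_depth = hp$base_depth, seed = seed),
        gaussian_nb = scoreGaussianNB(train, labels, test,
            var_smoothing = hp$var_smoothing),
        knn = scoreKnn(train, labels, test, k = hp$k),
        stop(sprintf("unknown algorithm: %s", spec@algorithm)))
}

# Tree-based scoring via ranger.  A probability forest averages per-tree
# class-1 probabilities; with num_trees = 1, mtry = p and no bootstrap it
# reduces to a single CART-style tree.
scoreRanger <- function(train, labels, test, num_trees, max_depth, mtry,
                        bootstrap, seed) {
    df <- as.data.frame(train)
    fit <- ranger::ranger(
        x = df, y = factor(labels, levels = c(0L, 1L)),
        num.trees = num_trees, mtry = mtry, max.depth = max_depth,
        splitrule = "gini", probability = TRUE,
        replace = bootstrap,
        sample.fraction = if (bootstrap) 1 else 1,
        num.threads = 1L, seed = as.integer(seed))
    pred <- stats::predict(fit, data = as.data.frame(test),
                           num.threads = 1L)$predictions
    unname(pred[, "1"])
}

scoreLinearSvm <- function(train, labels, test, cost) {
    y <- factor(labels, levels = c(0L, 1L))
    fit <- e1071::svm(x = train, y = y, kernel = "linear", cost = cost,
                      scale = FALSE)
    pr <- stats::predict(fit, test, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # decision value is oriented toward the first class in the column name
    first <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]][1L]
    if (first == "1") as.numeric(dv[, 1L]) else -as.numeric(dv[, 1L])
}

# Discrete AdaBoost (SAMME with two classes) over depth-limited rpart
# learners; the score is the staged decision sum in {-, +} orientation.
scoreAdaboost <- function(train, labels, test, n_estimators, learning_rate,
                          base_depth, seed) {
    n <- nrow(train)
    y <- ifelse(labels == 1L, 1, -1)
    df <- data.frame(train)
    df_test <- data.frame(test)
    w <- rep(1 / n, n)
    score <- numeric(nrow(test))
    ctrl <- rpart::rpart.control(maxdepth = base_depth, cp = 0,
                                 minsplit = 2L, minbucket = 1L, xval = 0L)
    withSeed(seed, {
        for (m in seq_len(n_estimators)) {
            dat <- cbind(.y = factor(y, levels = c(-1, 1)), df)
            fit <- rpart::rpart(.y ~ ., data = dat, weights = w,
                                method = "class", control = ctrl,
                                parms = list(split = "gini"))
            h_tr <- ifelse(stats::predict(fit, df, type = "class") == "1",
                           1, -1)
            err <- sum(w * (h_tr != y))
            err <- min(max(err, 1e-10), 1 - 1e-10)
            if (err >= 0.5 && m > 1L) break
            alpha <- learning_rate * 0.5 * log((1 - err) / err)
            h_te <- ifelse(stats::predict(fit, df_test,
                                          type = "class") == "1", 1, -1)
            score <- score + alpha * h_te
            w <- w * exp(-alpha * y * h_tr)
            w <- w / sum(w)
        }
    })
    score
}

# Gaussian class-conditional naive Bayes with additive variance smoothing
# (a fraction of the largest feature variance), applied even to the binary
# overlap features: the framework deliberately uses the Gaussian variant.
scoreGaussianNB <- function(train, labels, test, var_smoothing) {
    classes <- c(0L, 1L)
    p <- ncol(train)
    varAll <- apply(train, 2L, function(v) mean((v - mean(v))^2))
    eps <- var_smoothing * max(varAll, 1e-12)
    mu <- s2 <- matrix(0, nrow = 2L, ncol = p)
    prior <- numeric(2L)
    for (ci in 1:2) {
        rows <- train[labels == classes[ci], , drop = FALSE]
        prior[ci] <- nrow(rows) / nrow(train)
        mu[ci, ] <- colMeans(rows)
        s2[ci, ] <- apply(rows, 2L, function(v) mean((v - mean(v))^2)) + eps
    }
    loglik <- function(ci) {
        const <- -0.5 * sum(log(2 * pi * s2[ci, ]))
        apply(test, 1L, function(x)
            const - 0.5 * sum((x - mu[ci, ])^2 / s2[ci, ])) + log(prior[ci])
    }
    unname(loglik(2L) - loglik(1L))
}

# k-nearest-neighbour score: fraction of the k nearest training rows (by
# Euclidean distance) labeled 1; equidistant neighbours are taken in
# training-row order.
scoreKnn <- function(train, labels, test, k) {
    k <- min(k, nrow(train))
    d2 <- outer(rowSums(test^2), rowSums(train^2), "+") -
        2 * tcrossprod(test, train)
    apply(d2, 1L, function(row) {
        nn <- order(row, seq_along(row))[seq_len(k)]
        mean(labels[nn] == 1L)
    })
}
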