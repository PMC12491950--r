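# Monte Carlo cross-validated outcome prediction with a gradient-boosted
# tree learner and additive (SHAP) feature attribution.

# stratified train/test split indices for one repeat
stratifiedSplit <- function(labels, testFraction) {
    idx1 <- which(labels); idx0 <- which(!labels)
    nT1 <- max(1L, round(testFraction * length(idx1)))
    nT0 <- max(1L, round(testFraction * length(idx0)))
    test <- c(sample(idx1, nT1), sample(idx0, nT0))
    sort(test)
}

# encode a feature table (data.frame or matrix) as a numeric matrix for
# the booster; factors/characters become integer codes, logicals 0/1
encodeFeatures <- function(x) {
    if (is.matrix(x)) {
        storage.mode(x) <- "double"
        return(x)
    }
    x <- as.data.frame(x)
    cols <- lapply(seq_along(x), function(j) {
        v <- x[[j]]
        if (is.numeric(v)) as.numeric(v)
        else if (is.logical(v)) as.numeric(v)
        else as.numeric(factor(v))
    })
    m <- do.call(cbind, cols)
    colnames(m) <- names(x)
    m
}

trainBooster <- function(Xtr, ytr, innerSeed, maxRounds = 200) {
    # inner stratified validation fold for early stopping
    val <- withSeed(innerSeed, stratifiedSplit(ytr == 1, 0.2))
    fit <- setdiff(seq_along(ytr), val)
    dtr <- xgboost::xgb.DMatrix(Xtr[fit, , drop = FALSE],
                                label = ytr[fit])
    dva <- xgboost::xgb.DMatrix(Xtr[val, , drop = FALSE],
                                label = ytr[val])
    params <- list(objective = "binary:logistic", max_depth = 3,
                   eta = 0.1, subsample = 0.8, colsample_bytree = 0.8,
                   eval_metric = "logloss", nthread = 1,
                   seed = innerSeed %% 100000)
    xgboost::xgb.train(params = params, data = dtr, nrounds = maxRounds,
                       evals = list(val = dva),
                       early_stopping_rounds = 10, verbose = 0)
}

#' Additive feature attribution of a fitted booster
#'
#' Per-sample, per-feature SHAP contributions: together with the base value
#' (last column) they sum exactly to the model margin for each sample.
#'
#' @param booster a fitted `xgb.Booster`.
#' @param features numeric matrix of samples to explain.
#' @return matrix (samples x features + `BIAS` column).
#' @export
featureAttribution <- function(booster, features) {
    stats::predict(booster, features, predcontrib = TRUE)
}

#' Monte Carlo cross-validated prediction of a binary outcome
#'
#' Repeated stratified random train/test splits; on each repeat a
#' gradient-boosted tree classifier (shallow trees, early stopping on an
#' inner validation fold) is fit on the training split with the adjustment
#' covariates always appended to the feature set, and the test-set AUC is
#' recorded.  Split membership depends only on `labels`, `seed`,
#' `nRepeats` and `testFraction`, so reports for different feature sets
#' produced with the same settings are paired repeat-by-repeat.  Feature
#' attribution is summarized as the mean absolute SHAP contribution per
#' feature over test samples, averaged across repeats.
#'
#' @param features samples-by-features matrix or `data.frame`.
#' @param labels logical (or 0/1) outcome vector.
#' @param covariates optional `data.frame` of covariates appended to every
#'   feature set (e.g. age, sex, BMI, antibiotics).
#' @param group optional factor (sequencing library); entered as an
#'   integer-coded feature for the tree learner.
#' @param featureSet label for the report.
#' @param nRepeats number of Monte Carlo repeats (default 100).
#' @param testFraction held-out fraction per repeat (default 0.2).
#' @param seed integer master seed for the split stream.
#' @return an [MCCVReport-class].
#' @export
mccvPredict <- function(features, labels, covariates = NULL, group = NULL,
                        featureSet = "features", nRepeats = 100,
                        testFraction = 0.2, seed) {
    if (missing(seed)) stop("'seed' is required", call. = FALSE)
    if (is.numeric(labels)) labels <- labels == 1
    if (!is.logical(labels))
        stop("'labels' must be logical or 0/1", call. = FALSE)
    if (min(sum(labels), sum(!labels)) < 5)
        stop("minority class has fewer than 5 samples; cross-validation ",
             "is not advisable", call. = FALSE)
    X <- encodeFeatures(features)
    if (is.null(colnames(X)))
        colnames(X) <- paste0("f", seq_len(ncol(X)))
    if (!is.null(covariates)) {
        C <- encodeFeatures(covariates)
        colnames(C) <- paste0("cov_", colnames(C))
        X <- cbind(X, C)
    }
    if (!is.null(group))
        X <- cbind(X, library_group = as.numeric(factor(group)))
    n <- nrow(X)
    if (n != length(labels))
        stop("features and labels differ in length", call. = FALSE)
    nRepeats <- assertCount(nRepeats, "nRepeats", min = 1)
    splitSeeds <- withSeed(seed, sample.int(.Machine$integer.max - 1,
                                            2 * nRepeats))
    aucs <- numeric(nRepeats)
    attr_sum <- numeric(ncol(X))
    y <- as.numeric(labels)
    for (r in seq_len(nRepeats)) {
        test <- withSeed(splitSeeds[r], stratifiedSplit(labels,
                                                        testFraction))
        train <- setdiff(seq_len(n), test)
        if (length(unique(y[train])) < 2 || length(unique(y[test])) < 2)
            stop("a split lost one class; increase sample size",
                 call. = FALSE)
        bst <- withSeed(splitSeeds[nRepeats + r],
            trainBooster(X[train, , drop = FALSE], y[train],
                         innerSeed = splitSeeds[nRepeats + r]))
        pred <- stats::predict(bst, X[test, , drop = FALSE])
        aucs[r] <- aucScore(pred, labels[test])
        contrib <- featureAttribution(bst, X[test, , drop = FALSE])
        attr_sum <- attr_sum +
            colMeans(abs(contrib[, seq_len(ncol(X)), drop = FALSE]))
    }
    methods::new("MCCVReport", featureSet = featureSet, aucs = aucs,
                 attribution = stats::setNames(attr_sum / nRepeats,
                                               colnames(X)),
                 seed = as.integer(seed), nRepeats = nRepeats,
                 testFraction = testFraction, n = as.integer(n))
}

#' Paired comparison of two MCCV reports
#'
#' Two-sided Wilcoxon signed-rank test on the per-repeat AUC differences of
#' two reports produced with identical split settings (same seed, repeats
#' and test fraction, hence the same splits).
#'
#' @param a,b [MCCVReport-class] objects.
#' @return list with `p`, `medianDifference` (`a - b`), `statistic`, and a
#'   `note` when the reports are identical (no difference to test).
#' @export
compareFeatureSets <- function(a, b) {
    if (!methods::is(a, "MCCVReport") || !methods::is(b, "MCCVReport"))
        stop("inputs must be MCCVReport objects", call. = FALSE)
    if (a@seed != b@seed || a@nRepeats != b@nRepeats ||
        a@testFraction != b@testFraction || a@n != b@n)
        stop("reports are not paired: split settings differ", call. = FALSE)
    d <- a@aucs - b@aucs
    if (all(d == 0))
        return(list(p = NA_real_, medianDifference = 0,
                    statistic = NA_real_,
                    note = "identical reports: no difference to test"))
    ht <- suppressWarnings(stats::wilcox.test(a@aucs, b@aucs,
                                              paired = TRUE,
                                              exact = FALSE))
    list(p = ht$p.value, medianDifference = stats::median(d),
         statistic = unname(ht$statistic))
}

#' Median AUC of an MCCV report
#' @param x an [MCCVReport-class].
#' @export
medianAUC <- function(x) stats::median(x@aucs)

setMethod("show", "MCCVReport", function(object) {
    cat("MCCVReport [", object@featureSet, "]: ", object@nRepeats,
        " repeats, n = ", object@n, "\n", sep = "")
    cat("  median AUC = ", round(stats::median(object@aucs), 3),
        " (IQR ", paste(round(stats::quantile(object@aucs, c(0.25, 0.75)),
                              3), collapse = "-"), ")\n", sep = "")
    top <- utils::head(sort(object@attribution, decreasing = TRUE), 5)
    cat("  top features:", paste(names(top), collapse = ", "), "\n")
    invisible(object)
})
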