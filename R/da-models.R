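# Three differential-abundance model families sharing one covariate and
# random-intercept interface.  Each operates on a different abundance scale:
#   - bias-corrected log-linear: log counts with an estimated per-sample
#     sampling-fraction offset removed (ANCOM-BC model family);
#   - CLR linear: centered log-ratio abundances with a mode-based
#     compositional bias correction of the coefficients (LinDA family);
#   - TSS log-linear: log total-sum-scaled relative abundances with a
#     half-minimum pseudocount (MaAsLin family).
# These are model-family re-implementations, not ports of the named
# packages; no numeric identity with them is claimed.

# taxa entering DA: present (count > 0) in at least minPrevalence of samples
prevalentTaxa <- function(counts, minPrevalence) {
    prev <- colMeans(counts > 0)
    colnames(counts)[prev >= minPrevalence]
}

# Design matrix and fitting plan shared by the three DA models.
buildDADesign <- function(metadata, group, contrast, reference, covariates,
                          randomIntercept) {
    metadata <- as.data.frame(metadata)
    if (!group %in% names(metadata))
        stop("group column '", group, "' not found", call. = FALSE)
    g <- factor(metadata[[group]])
    if (!contrast %in% levels(g) || !reference %in% levels(g))
        stop("contrast and reference must be levels of '", group, "'",
             call. = FALSE)
    if (min(table(g)[c(contrast, reference)]) < 2)
        stop("each contrast level needs at least 2 samples", call. = FALSE)
    g <- stats::relevel(g, ref = reference)
    df <- data.frame(.group = g)
    covariates <- covariates[covariates %in% names(metadata)]
    for (cv in covariates) df[[cv]] <- metadata[[cv]]
    useMixed <- FALSE
    if (!is.null(randomIntercept)) {
        if (!randomIntercept %in% names(metadata))
            stop("random-intercept column '", randomIntercept,
                 "' not found", call. = FALSE)
        lib <- factor(metadata[[randomIntercept]])
        if (nlevels(lib) >= 3) {
            useMixed <- TRUE
            df$.lib <- lib
        } else if (nlevels(lib) == 2) {
            # too few batches for a variance component: fixed batch term
            df$.lib <- lib
            covariates <- c(covariates, ".lib")
        }
    }
    fixedTerms <- c(".group", covariates)
    X <- stats::model.matrix(stats::reformulate(fixedTerms), data = df)
    coefName <- paste0(".group", contrast)
    if (!coefName %in% colnames(X))
        stop("contrast level '", contrast, "' absent from design",
             call. = FALSE)
    list(X = X, df = df, useMixed = useMixed, coefName = coefName,
         fixedTerms = fixedTerms)
}

# Vectorized OLS of every column of Y on X; returns the contrast
# coefficient, its se and t-test p per column.
olsAcrossTaxa <- function(Y, X, coefName) {
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
        keep <- qrX$pivot[seq_len(qrX$rank)]
        X <- X[, keep, drop = FALSE]
        if (!coefName %in% colnames(X))
            stop("contrast coefficient aliased in rank-deficient design",
                 call. = FALSE)
        qrX <- qr(X)
    }
    B <- qr.coef(qrX, Y)
    fitted <- X %*% B
    res <- Y - fitted
    df <- nrow(X) - qrX$rank
    sigma2 <- colSums(res^2) / df
    xtxinv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot),
                                  drop = FALSE]
    cc <- xtxinv[match(coefName, colnames(X)), match(coefName, colnames(X))]
    beta <- B[coefName, ]
    se <- sqrt(sigma2 * cc)
    tt <- ifelse(se > 0, beta / se, 0)
    p <- 2 * stats::pt(-abs(tt), df)
    p[se == 0 & abs(beta) < 1e-10] <- 1
    list(beta = beta, se = se, p = p, df = df, B = B, fitted = fitted)
}

# Per-taxon linear mixed model with a library random intercept; Wald
# normal-approximation p-values.
mixedAcrossTaxa <- function(Y, df, fixedTerms, coefName) {
    form <- stats::as.formula(paste(".y ~",
        paste(fixedTerms, collapse = " + "), "+ (1 | .lib)"))
    m <- ncol(Y)
    beta <- se <- p <- rep(NA_real_, m)
    for (j in seq_len(m)) {
        dj <- df
        dj$.y <- Y[, j]
        fit <- suppressMessages(suppressWarnings(
            lme4::lmer(form, data = dj, REML = TRUE,
                       control = lme4::lmerControl(
                           check.conv.singular = "ignore"))))
        fe <- lme4::fixef(fit)
        vc <- as.matrix(stats::vcov(fit))
        k <- match(coefName, names(fe))
        beta[j] <- fe[k]
        se[j] <- sqrt(vc[k, k])
        z <- if (se[j] > 0) beta[j] / se[j] else 0
        p[j] <- 2 * stats::pnorm(-abs(z))
        if (se[j] == 0 && abs(beta[j]) < 1e-10) p[j] <- 1
    }
    list(beta = beta, se = se, p = p)
}

# Common driver: transform -> fit -> (optional coefficient correction) ->
# BH adjust -> DAResult.
fitDAModel <- function(x, metadata, group, contrast, reference, covariates,
                       randomIntercept, minPrevalence, method, transform,
                       correct = NULL, removeSamplingFractions = FALSE) {
    counts <- if (methods::is(x, "MicrobiomeExperiment"))
        countMatrix(x, samplesAsRows = TRUE) else as.matrix(x)
    if (is.null(metadata) && methods::is(x, "MicrobiomeExperiment"))
        metadata <- sampleData(x)
    if (any(rowSums(counts) == 0))
        stop("all-zero sample(s): sampling fractions unestimable",
             call. = FALSE)
    taxa <- prevalentTaxa(counts, minPrevalence)
    if (length(taxa) == 0)
        stop("no taxa pass the prevalence filter", call. = FALSE)
    counts <- counts[, taxa, drop = FALSE]
    if (identical(contrast, reference)) {
        tb <- data.frame(taxon = taxa, lfc = 0, se = 0, p = 1, q = 1)
        return(methods::new("DAResult", method = method, contrast = contrast,
                            reference = reference, table = tb))
    }
    des <- buildDADesign(metadata, group, contrast, reference, covariates,
                         randomIntercept)
    Y <- transform(counts)
    if (removeSamplingFractions) {
        Xd <- des$X
        if (des$useMixed)
            Xd <- cbind(Xd, stats::model.matrix(~ .lib, des$df)[, -1,
                                                                drop = FALSE])
        Y <- Y - estimateSamplingFractions(Y, Xd, counts)
    }
    fit <- if (des$useMixed)
        mixedAcrossTaxa(Y, des$df, des$fixedTerms, des$coefName)
    else
        olsAcrossTaxa(Y, des$X, des$coefName)
    if (!is.null(correct)) fit <- correct(fit, Y, des)
    q <- bhAdjust(fit$p)
    tb <- data.frame(taxon = taxa, lfc = unname(fit$beta),
                     se = unname(fit$se), p = unname(fit$p), q = unname(q),
                     row.names = NULL)
    methods::new("DAResult", method = method, contrast = contrast,
                 reference = reference, table = tb)
}

#' Bias-corrected log-linear differential abundance
#'
#' Log-linear model on observed log counts in which each sample's unknown
#' sampling fraction (the offset between true and observed log abundances)
#' is estimated as a per-sample intercept by alternating least squares over
#' the high-prevalence taxa and removed before the final fit; any residual
#' common shift of the group coefficients is then removed at the mode of
#' their across-taxa distribution.  Per-taxon Wald tests with BH
#' adjustment across tested taxa (ANCOM-BC model family).
#'
#' @param x a [MicrobiomeExperiment-class] or samples-by-taxa count matrix.
#' @param metadata per-sample `data.frame`; defaults to `colData` of `x`.
#' @param group metadata column with the diagnosis factor.
#' @param contrast group level whose log fold change is reported.
#' @param reference reference group level.
#' @param covariates adjustment covariate columns.
#' @param randomIntercept metadata column treated as a random intercept
#'   (sequencing library); a variance component when it has >= 3 levels,
#'   a fixed term with 2, ignored with 1.
#' @param minPrevalence taxa present in at least this fraction of samples
#'   enter the model (default 0.1).
#' @param pseudocount offset added to counts before the log (default 1).
#' @return a [DAResult-class].
#' @export
daBiasCorrectedLogLinear <- function(x, metadata = NULL,
        group = "diagnosis", contrast, reference,
        covariates = c("age", "sex", "antibiotics", "sampling_delay"),
        randomIntercept = "library", minPrevalence = 0.1, pseudocount = 1) {
    fitDAModel(x, metadata, group, contrast, reference, covariates,
               randomIntercept, minPrevalence,
               method = "bias_corrected_loglinear",
               transform = function(counts) log(counts + pseudocount),
               correct = correctByMode,
               removeSamplingFractions = TRUE)
}

# Alternating-least-squares estimate of per-sample sampling fractions d:
# jointly minimizes || Y - 1 d' - X B ||_F over (d, B), identified by
# centering d.  Only high-prevalence taxa inform d: for them the log-count
# response to a sampling-fraction change is linear, whereas taxa with many
# zeros respond attenuated and would bias the offset.  The library term
# (when present) is absorbed into X here so batch structure does not leak
# into d.
estimateSamplingFractions <- function(Y, X, counts, maxit = 50,
                                      tol = 1e-8, minPrev = 0.9) {
    prev <- colMeans(counts > 0)
    use <- which(prev >= minPrev)
    if (length(use) < min(20, ncol(Y)))
        use <- order(prev, decreasing = TRUE)[seq_len(min(20, ncol(Y)))]
    Yd <- Y[, use, drop = FALSE]
    qrX <- qr(X)
    d <- numeric(nrow(Y))
    for (it in seq_len(maxit)) {
        B <- qr.coef(qrX, Yd - d)
        B[is.na(B)] <- 0
        dNew <- rowMeans(Yd - X %*% B)
        dNew <- dNew - mean(dNew)
        if (max(abs(dNew - d)) < tol) { d <- dNew; break }
        d <- dNew
    }
    d
}

#' Centered log-ratio linear differential abundance
#'
#' Linear models on CLR-transformed abundances with a compositional bias
#' correction: the per-taxon group coefficients are shifted by the mode of
#' their distribution across taxa (kernel density estimate), reflecting the
#' assumption that most taxa are not differential; t-tests on the corrected
#' coefficients with BH adjustment (LinDA model family).
#'
#' @inheritParams daBiasCorrectedLogLinear
#' @param pseudocount CLR pseudocount (default 0.5).
#' @return a [DAResult-class].
#' @export
daClrLinear <- function(x, metadata = NULL, group = "diagnosis", contrast,
        reference,
        covariates = c("age", "sex", "antibiotics", "sampling_delay"),
        randomIntercept = "library", minPrevalence = 0.1,
        pseudocount = 0.5) {
    fitDAModel(x, metadata, group, contrast, reference, covariates,
               randomIntercept, minPrevalence, method = "clr_linear",
               transform = function(counts) clrTransform(counts, pseudocount),
               correct = correctByMode)
}

#' TSS log-linear differential abundance
#'
#' Linear models on log total-sum-scaled relative abundances with a
#' half-minimum pseudocount (half the smallest non-zero relative abundance
#' in the table); t-tests with BH adjustment (MaAsLin model family).
#'
#' @inheritParams daBiasCorrectedLogLinear
#' @return a [DAResult-class].
#' @export
daTssLogLinear <- function(x, metadata = NULL, group = "diagnosis", contrast,
        reference,
        covariates = c("age", "sex", "antibiotics", "sampling_delay"),
        randomIntercept = "library", minPrevalence = 0.1) {
    fitDAModel(x, metadata, group, contrast, reference, covariates,
               randomIntercept, minPrevalence, method = "tss_log_linear",
               transform = function(counts) {
                   rel <- counts / rowSums(counts)
                   eps <- 0.5 * min(rel[rel > 0])
                   log(rel + eps)
               },
               correct = NULL)
}

# LinDA-style mode correction: subtract the kernel-density mode of the
# coefficient distribution across taxa, then recompute p from the shifted
# coefficients.
correctByMode <- function(fit, Y, des) {
    beta <- fit$beta
    if (length(beta) >= 10) {
        dens <- stats::density(beta, na.rm = TRUE)
        shift <- dens$x[which.max(dens$y)]
    } else shift <- stats::median(beta, na.rm = TRUE)
    beta <- beta - shift
    se <- fit$se
    df <- if (!is.null(fit$df)) fit$df else Inf
    tt <- ifelse(se > 0, beta / se, 0)
    p <- 2 * stats::pt(-abs(tt), df)
    p[se == 0 & abs(beta) < 1e-10] <- 1
    list(beta = beta, se = se, p = p, df = fit$df)
}

setMethod("show", "DAResult", function(object) {
    tb <- object@table
    cat("DAResult [", object@method, "] ", object@contrast, " vs ",
        object@reference, " (reference)\n", sep = "")
    cat("  ", nrow(tb), " taxa tested, ", sum(tb$q < 0.05, na.rm = TRUE),
        " at q < 0.05\n", sep = "")
    invisible(object)
})
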