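#' Shannon diversity (natural log)
#'
#' `H = -sum(p_i * log(p_i))` over taxa with positive abundance, in nats.
#'
#' @param x a count vector, a samples-by-taxa matrix, or a
#'   [MicrobiomeExperiment-class].
#' @return numeric: one value per sample.
#' @export
shannon <- function(x) {
    m <- if (methods::is(x, "MicrobiomeExperiment"))
        countMatrix(x, samplesAsRows = TRUE)
    else if (is.matrix(x)) x
    else matrix(x, nrow = 1)
    if (any(rowSums(m) <= 0))
        stop("zero-total sample(s) have undefined diversity", call. = FALSE)
    vegan::diversity(m, index = "shannon", base = exp(1))
}

#' Observed-taxon richness
#'
#' Number of taxa with count >= 1 per sample; intended for rarefied data so
#' richness is comparable across samples.
#'
#' @inheritParams shannon
#' @export
observedTaxa <- function(x) {
    m <- if (methods::is(x, "MicrobiomeExperiment"))
        countMatrix(x, samplesAsRows = TRUE)
    else if (is.matrix(x)) x
    else matrix(x, nrow = 1)
    rowSums(m >= 1)
}

#' Per-sample alpha diversity table
#'
#' @param x a rarefied [MicrobiomeExperiment-class].
#' @return `data.frame` with `sample_id`, `shannon` (nats), `observed_taxa`.
#' @export
alphaDiversity <- function(x) {
    data.frame(sample_id = colnames(x),
               shannon = as.numeric(shannon(x)),
               observed_taxa = as.integer(observedTaxa(x)),
               row.names = NULL)
}

#' Bray-Curtis dissimilarity
#'
#' `BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i)`.  Intended for rarefied
#' tables; with unequal sample depths a warning is raised (or an error when
#' `requireEqualDepth = TRUE`).
#'
#' @param x a [MicrobiomeExperiment-class] or samples-by-taxa matrix.
#' @param requireEqualDepth escalate the unequal-depth warning to an error.
#' @return a `dist` object over samples.
#' @export
brayCurtis <- function(x, requireEqualDepth = FALSE) {
    m <- if (methods::is(x, "MicrobiomeExperiment"))
        countMatrix(x, samplesAsRows = TRUE) else as.matrix(x)
    tot <- rowSums(m)
    if (length(unique(tot)) > 1) {
        msg <- "samples have unequal depths; rarefy before Bray-Curtis"
        if (requireEqualDepth) stop(msg, call. = FALSE) else warning(msg,
            call. = FALSE)
    }
    vegan::vegdist(m, method = "bray")
}

# all permutations of seq_len(n) as a matrix (n <= 8), identity excluded
allPermutations <- function(n) {
    perms <- function(v) {
        if (length(v) == 1) return(matrix(v, 1))
        out <- NULL
        for (i in seq_along(v))
            out <- rbind(out, cbind(v[i], perms(v[-i])))
        out
    }
    p <- perms(seq_len(n))
    p[rowSums(p == matrix(seq_len(n), nrow(p), n, byrow = TRUE)) != n, ,
      drop = FALSE]
}

#' PERMANOVA on a dissimilarity matrix
#'
#' Permutational multivariate analysis of variance: partitions the sum of
#' squares of a dissimilarity matrix by the model terms (covariates first,
#' the group factor last, sequentially) and tests the group pseudo-F by
#' permuting sample labels.  The permutation p-value uses the
#' `(1 + b) / (1 + m)` convention so it is never zero.  With
#' `nPermutations = "exact"` all label permutations are enumerated (small
#' designs only), making the p-value permutation-exact.
#'
#' @param d a `dist` or square symmetric matrix of dissimilarities.
#' @param groups factor of group labels, one per sample.
#' @param covariates optional `data.frame` of adjustment covariates,
#'   entered before the group term.
#' @param nPermutations number of label permutations (default 999), or
#'   `"exact"`.
#' @param seed integer seed for the permutation stream.
#' @return a [PermTestResult-class] for the group term.
#' @export
permanova <- function(d, groups, covariates = NULL, nPermutations = 999,
                      seed = 1) {
    d <- stats::as.dist(d)
    n <- attr(d, "Size")
    groups <- factor(groups)
    if (length(groups) != n)
        stop("length of 'groups' must match the dissimilarity matrix",
             call. = FALSE)
    if (any(table(groups) < 2))
        stop("every group needs at least 2 samples", call. = FALSE)
    df <- data.frame(.group = groups)
    rhs <- ".group"
    if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
        covariates <- as.data.frame(covariates)
        df <- cbind(covariates, df)
        rhs <- c(names(covariates), ".group")
    }
    form <- stats::reformulate(rhs, response = quote(d))
    environment(form) <- environment()
    exact <- identical(nPermutations, "exact")
    perm <- if (exact) {
        if (n > 8)
            stop("exact enumeration supported only for n <= 8",
                 call. = FALSE)
        allPermutations(n)
    } else assertCount(nPermutations, "nPermutations", min = 1)
    res <- withSeed(seed, vegan::adonis2(form, data = df,
                                         permutations = perm,
                                         by = "terms"))
    row <- which(rownames(res) == ".group")
    nPerm <- if (exact) nrow(perm) else perm
    methods::new("PermTestResult", method = "PERMANOVA", term = "group",
                 statistic = res$F[row], rSquared = res$R2[row],
                 p = res$`Pr(>F)`[row], nPermutations = as.integer(nPerm))
}

#' PERMDISP: homogeneity of multivariate dispersions
#'
#' Per-group distances to the group's spatial median in principal-coordinate
#' space, compared across groups by an F statistic with a permutation
#' p-value.
#'
#' @inheritParams permanova
#' @return a [PermTestResult-class].
#' @export
permdisp <- function(d, groups, nPermutations = 999, seed = 1) {
    d <- stats::as.dist(d)
    groups <- factor(groups)
    if (any(table(groups) < 2))
        stop("every group needs at least 2 samples", call. = FALSE)
    nPermutations <- assertCount(nPermutations, "nPermutations", min = 1)
    mod <- vegan::betadisper(d, groups, type = "median")
    pt <- withSeed(seed,
        vegan::permutest(mod, permutations = nPermutations))
    tab <- pt$tab
    ssGroups <- tab$`Sum Sq`[1]
    r2 <- ssGroups / sum(tab$`Sum Sq`)
    methods::new("PermTestResult", method = "PERMDISP", term = "group",
                 statistic = tab$F[1], rSquared = r2,
                 p = tab$`Pr(>F)`[1],
                 nPermutations = as.integer(nPermutations))
}

#' Group distances to spatial medians (PERMDISP diagnostics)
#'
#' @inheritParams permdisp
#' @return numeric vector of each sample's distance to its group's spatial
#'   median.
#' @export
dispersionDistances <- function(d, groups) {
    mod <- vegan::betadisper(stats::as.dist(d), factor(groups),
                             type = "median")
    mod$distances
}

setMethod("show", "PermTestResult", function(object) {
    cat(object@method, "on term '", object@term, "': F = ",
        signif(object@statistic, 4), ", R2 = ", signif(object@rSquared, 4),
        ", p = ", signif(object@p, 4), " (", object@nPermutations,
        " permutations)\n", sep = "")
    invisible(object)
})

#' Covariate-adjusted alpha-diversity comparison
#'
#' Linear (Gaussian generalized linear) model of a per-sample diversity
#' value on the diagnosis group plus adjustment covariates; reports the
#' effect estimate, standard error and p-value of each non-reference group
#' level.  Constant or collinear covariates are dropped with a warning.
#'
#' @param alpha numeric per-sample diversity values.
#' @param metadata `data.frame` aligned with `alpha` containing `group` and
#'   the covariates.
#' @param group metadata column holding the group factor
#'   (default `"diagnosis"`).
#' @param reference reference level (default: first level).
#' @param covariates character vector of covariate column names; default
#'   age, sex, BMI and antibiotics exposure.
#' @return `data.frame`: one row per contrast with `contrast`, `estimate`,
#'   `se`, `p`.
#' @export
compareAlpha <- function(alpha, metadata, group = "diagnosis",
                         reference = NULL,
                         covariates = c("age", "sex", "bmi", "antibiotics")) {
    metadata <- as.data.frame(metadata)
    if (!group %in% names(metadata))
        stop("group column '", group, "' not found", call. = FALSE)
    miss <- setdiff(covariates, names(metadata))
    if (length(miss) > 0)
        stop("covariate(s) not in metadata: ", paste(miss, collapse = ", "),
             call. = FALSE)
    g <- factor(metadata[[group]])
    if (!is.null(reference)) g <- stats::relevel(g, ref = reference)
    keep <- character(0)
    for (cv in covariates) {
        v <- metadata[[cv]]
        if (length(unique(v[!is.na(v)])) < 2) {
            warning("dropping constant covariate '", cv, "'", call. = FALSE)
        } else keep <- c(keep, cv)
    }
    df <- data.frame(.alpha = alpha, .group = g,
                     metadata[, keep, drop = FALSE])
    fit <- stats::glm(stats::reformulate(c(".group", keep),
                                         response = ".alpha"),
                      data = df, family = stats::gaussian())
    dropped <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    if (length(dropped) > 0)
        warning("collinear term(s) dropped: ",
                paste(dropped, collapse = ", "), call. = FALSE)
    sm <- summary(fit)$coefficients
    rows <- grep("^\\.group", rownames(sm))
    data.frame(contrast = paste(sub("^\\.group", "", rownames(sm)[rows]),
                                "vs", levels(g)[1]),
               estimate = sm[rows, 1], se = sm[rows, 2],
               p = sm[rows, 4], row.names = NULL)
}

#' Two-sample rank test utility
#'
#' Wilcoxon-Mann-Whitney comparison of a numeric value (e.g. a principal
#' coordinate) between two groups.
#'
#' @param values numeric vector.
#' @param groups two-level factor.
#' @return list with `statistic` (U), `p`.
#' @export
rankTest <- function(values, groups) {
    groups <- factor(groups)
    if (nlevels(groups) != 2)
        stop("exactly two groups required", call. = FALSE)
    ht <- stats::wilcox.test(values ~ groups, exact = FALSE)
    list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Principal coordinates of a dissimilarity matrix
#'
#' Classical multidimensional scaling; returns sample scores for the first
#' `k` axes together with the fraction of variance each explains.
#'
#' @param d a `dist`.
#' @param k number of axes (default 2).
#' @return list with `scores` (n x k matrix) and `varExplained`.
#' @export
principalCoordinates <- function(d, k = 2) {
    d <- stats::as.dist(d)
    fit <- stats::cmdscale(d, k = k, eig = TRUE)
    pos <- fit$eig[fit$eig > 0]
    list(scores = fit$points,
         varExplained = fit$eig[seq_len(k)] / sum(pos))
}
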