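#' Build the UC-CD index from a consensus result
#'
#' The index taxa are the consensus hits of a UC-vs-CD contrast: taxa with
#' positive log fold change toward UC form the overrepresented (`up`) set,
#' negative ones the underrepresented (`down`) set.
#'
#' @param consensus a [DAConsensus-class] from a UC-vs-CD contrast.
#' @param epsilon pseudocount on the relative-abundance scale added to both
#'   sums when the index is applied (default `1e-6`).
#' @return an [IndexDefinition-class] with provenance recording the
#'   contrast, reference and alpha.
#' @export
buildIndex <- function(consensus, epsilon = 1e-6) {
    if (!methods::is(consensus, "DAConsensus"))
        stop("'consensus' must be a DAConsensus", call. = FALSE)
    sm <- consensus@summary
    up <- sm$taxon[sm$consensus & sm$direction > 0]
    down <- sm$taxon[sm$consensus & sm$direction < 0]
    if (length(up) == 0 || length(down) == 0)
        stop("cannot build an index: need consensus taxa in both ",
             "directions (", length(up), " up, ", length(down), " down); ",
             "an index from a one-sided or empty consensus is not ",
             "meaningful", call. = FALSE)
    methods::new("IndexDefinition", upTaxa = up, downTaxa = down,
                 epsilon = epsilon,
                 provenance = list(contrast = consensus@contrast,
                                   reference = consensus@reference,
                                   alpha = consensus@alpha))
}

#' Apply the UC-CD index to a cohort
#'
#' Per sample, `I = ln((sum of up-taxon relative abundances + eps) /
#' (sum of down-taxon relative abundances + eps))`.  Taxa are matched on
#' normalized genus keys ([normalizeTaxonNames]) so the index transfers
#' across cohorts with different label conventions; index taxa absent from
#' the cohort contribute zero to their sum, and the fraction of index taxa
#' found is reported as coverage.
#'
#' @param def an [IndexDefinition-class].
#' @param x a [MicrobiomeExperiment-class], or a samples-by-taxa matrix of
#'   counts or relative abundances (rows are normalized internally).
#' @return an [IndexScores-class]; flagged unusable when coverage is zero.
#' @export
applyIndex <- function(def, x) {
    rel <- toRelative(x)
    keys <- normalizeTaxonNames(colnames(rel))
    upKeys <- normalizeTaxonNames(def@upTaxa)
    downKeys <- normalizeTaxonNames(def@downTaxa)
    upIdx <- which(keys %in% upKeys)
    downIdx <- which(keys %in% downKeys)
    nFound <- sum(upKeys %in% keys) + sum(downKeys %in% keys)
    coverage <- nFound / (length(upKeys) + length(downKeys))
    upSum <- if (length(upIdx) > 0)
        rowSums(rel[, upIdx, drop = FALSE]) else numeric(nrow(rel))
    downSum <- if (length(downIdx) > 0)
        rowSums(rel[, downIdx, drop = FALSE]) else numeric(nrow(rel))
    scores <- log((upSum + def@epsilon) / (downSum + def@epsilon))
    usable <- coverage > 0
    if (!usable)
        warning("no index taxa found in this cohort; scores are flagged ",
                "unusable", call. = FALSE)
    methods::new("IndexScores",
                 scores = stats::setNames(scores, rownames(rel)),
                 coverage = coverage, usable = usable)
}

#' Area under the ROC curve
#'
#' Probability that a randomly chosen positive sample outranks a randomly
#' chosen negative one, with ties counted one half (the normalized
#' Mann-Whitney U / midrank identity).
#'
#' @param scores numeric scores.
#' @param labels binary labels (logical, 0/1, or two-level factor);
#'   `positive` names the positive level for factors/characters.
#' @param positive positive class for non-logical labels.
#' @return AUC in `[0, 1]`.
#' @export
aucScore <- function(scores, labels, positive = NULL) {
    if (is.logical(labels)) {
        pos <- labels
    } else if (is.numeric(labels) && all(labels %in% c(0, 1))) {
        pos <- labels == 1
    } else {
        labels <- as.character(labels)
        if (is.null(positive))
            stop("'positive' must name the positive class", call. = FALSE)
        pos <- labels == positive
    }
    ok <- !is.na(scores) & !is.na(pos)
    scores <- scores[ok]; pos <- pos[ok]
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0)
        stop("both classes must be present", call. = FALSE)
    r <- rank(scores)  # midranks
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Disease-location gradient of the index
#'
#' Covariate-adjusted linear models of the index on disease-location
#' contrasts along the clinical colonic continuum: ileal CD (`L1`) vs
#' colonic CD (`L2`), colonic CD vs UC, and an ordinal trend test across
#' the ordering `L1 < L3 < L2 < E1 < E2 < E3` (the trend test goes beyond
#' the pairwise contrasts and is labelled as such in the output).
#'
#' @param scores an [IndexScores-class] or named numeric vector.
#' @param metadata `data.frame` with `montreal_location`, `diagnosis` and
#'   covariate columns; aligned by sample id when `scores` is named.
#' @param covariates adjustment covariates (default age, sex, BMI,
#'   antibiotics).
#' @return `data.frame`: one row per contrast/test with `test`, `contrast`,
#'   `estimate`, `se`, `p`, `n`.
#' @export
locationGradient <- function(scores, metadata,
                             covariates = c("age", "sex", "bmi",
                                            "antibiotics")) {
    s <- if (methods::is(scores, "IndexScores")) scores@scores else scores
    metadata <- as.data.frame(metadata)
    if (!is.null(names(s)) && "sample_id" %in% names(metadata))
        metadata <- metadata[match(names(s), metadata$sample_id), ,
                             drop = FALSE]
    if (!"montreal_location" %in% names(metadata))
        stop("metadata must contain 'montreal_location'", call. = FALSE)
    loc <- as.character(metadata$montreal_location)
    covariates <- covariates[covariates %in% names(metadata)]
    fitContrast <- function(sel, labelA, labelB, groupVar) {
        dat <- data.frame(.y = s[sel], .g = factor(groupVar[sel],
                                                   levels = c(labelB,
                                                              labelA)),
                          metadata[sel, covariates, drop = FALSE])
        fit <- stats::lm(stats::reformulate(c(".g", covariates),
                                            response = ".y"), data = dat)
        sm <- summary(fit)$coefficients
        row <- grep("^\\.g", rownames(sm))[1]
        data.frame(test = "linear_contrast",
                   contrast = paste(labelA, "vs", labelB),
                   estimate = sm[row, 1], se = sm[row, 2], p = sm[row, 4],
                   n = sum(sel), row.names = NULL)
    }
    out <- list()
    isUC <- metadata$diagnosis == "UC"
    selIleoCol <- loc %in% c("L1_ileal", "L2_colonic")
    if (all(c("L1_ileal", "L2_colonic") %in% loc[selIleoCol]))
        out$ileal <- fitContrast(selIleoCol, "L2_colonic", "L1_ileal", loc)
    else warning("contrast level absent: skipping colonic-vs-ileal CD",
                 call. = FALSE)
    selUCcol <- loc == "L2_colonic" | isUC
    grp <- ifelse(isUC, "UC", loc)
    if (any(loc == "L2_colonic") && any(isUC))
        out$uccol <- fitContrast(selUCcol, "UC", "L2_colonic", grp)
    else warning("contrast level absent: skipping UC-vs-colonic CD",
                 call. = FALSE)
    ordering <- c(L1_ileal = 1, L3_ileocolonic = 2, L2_colonic = 3,
                  E1_proctitis = 4, E2_left_sided = 5, E3_total = 6)
    selTrend <- loc %in% names(ordering)
    if (sum(selTrend) >= 3 && length(unique(loc[selTrend])) >= 2) {
        dat <- data.frame(.y = s[selTrend],
                          .t = unname(ordering[loc[selTrend]]),
                          metadata[selTrend, covariates, drop = FALSE])
        fit <- stats::lm(stats::reformulate(c(".t", covariates),
                                            response = ".y"), data = dat)
        sm <- summary(fit)$coefficients
        out$trend <- data.frame(test = "ordinal_trend",
                                contrast = "L1<L3<L2<E1<E2<E3",
                                estimate = sm[".t", 1], se = sm[".t", 2],
                                p = sm[".t", 4], n = sum(selTrend),
                                row.names = NULL)
    }
    do.call(rbind, out)
}

#' Serialize / read an index definition
#'
#' The definition is stored as a small JSON document with fields `up_taxa`,
#' `down_taxa`, `epsilon`, `provenance`.
#'
#' @param def an [IndexDefinition-class].
#' @param path file path.
#' @name indexIO
#' @export
writeIndexDefinition <- function(def, path) {
    jsonlite::write_json(
        list(up_taxa = def@upTaxa, down_taxa = def@downTaxa,
             epsilon = def@epsilon, provenance = def@provenance),
        path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
}

#' @rdname indexIO
#' @export
readIndexDefinition <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    methods::new("IndexDefinition", upTaxa = x$up_taxa,
                 downTaxa = x$down_taxa, epsilon = x$epsilon,
                 provenance = as.list(x$provenance))
}

setMethod("show", "IndexDefinition", function(object) {
    cat("UC-CD IndexDefinition: ", length(object@upTaxa), " up / ",
        length(object@downTaxa), " down taxa, epsilon = ", object@epsilon,
        "\n", sep = "")
    pv <- object@provenance
    if (length(pv) > 0)
        cat("  provenance: ", pv$contrast, " vs ", pv$reference,
            ", alpha = ", pv$alpha, "\n", sep = "")
    invisible(object)
})

setMethod("show", "IndexScores", function(object) {
    cat("IndexScores: ", length(object@scores), " samples, coverage = ",
        round(object@coverage, 3),
        if (!object@usable) " (UNUSABLE: zero coverage)" else "", "\n",
        sep = "")
    invisible(object)
})
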