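#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   colData<- rowData
NULL

#' MicrobiomeExperiment: genus-level counts with sample metadata
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with a validated
#' `"counts"` assay of non-negative integer read counts, stored taxa-by-samples
#' as is conventional for Bioconductor assay containers.  Per-sample clinical
#' and technical covariates live in `colData`; the verbatim taxonomy string and
#' its normalized genus key live in `rowData`.  On-disk tables written or read
#' by this package are oriented samples-as-rows (see [readCountTable]).
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @export
setClass("MicrobiomeExperiment", contains = "SummarizedExperiment")

setValidity("MicrobiomeExperiment", function(object) {
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("assay 'counts' is required")
    m <- SummarizedExperiment::assay(object, "counts")
    if (any(is.na(m)))
        return("counts contain NA")
    if (any(m < 0))
        return("counts contain negative entries")
    if (any(abs(m - round(m)) > 1e-8))
        return("counts contain non-integer entries")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        return("taxon identifiers must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        return("sample identifiers must be present and unique")
    TRUE
})

#' Result of a permutation test on a dissimilarity matrix
#'
#' Holds the observed statistic, variance-explained fraction and permutation
#' p-value from a PERMANOVA or PERMDISP test.
#'
#' @slot method character, `"PERMANOVA"` or `"PERMDISP"`.
#' @slot term character, the tested term (the group factor).
#' @slot statistic numeric, pseudo-F (PERMANOVA) or dispersion F (PERMDISP).
#' @slot rSquared numeric, fraction of total sum of squares for the term.
#' @slot p numeric permutation p-value, `(1 + b) / (1 + m)` convention.
#' @slot nPermutations integer, number of permutations used.
#' @export
setClass("PermTestResult",
    representation(method = "character", term = "character",
                   statistic = "numeric", rSquared = "numeric",
                   p = "numeric", nPermutations = "integer"))

setValidity("PermTestResult", function(object) {
    if (length(object@p) == 1 && !is.na(object@p) &&
        (object@p <= 0 || object@p > 1))
        return("p must be in (0, 1]")
    if (length(object@rSquared) == 1 && !is.na(object@rSquared) &&
        (object@rSquared < -1e-8 || object@rSquared > 1 + 1e-8))
        return("rSquared must be in [0, 1]")
    TRUE
})

#' Per-taxon result of one differential-abundance model
#'
#' @slot method one of `"bias_corrected_loglinear"`, `"clr_linear"`,
#'   `"tss_log_linear"`.
#' @slot contrast character, the group level whose effect is reported.
#' @slot reference character, the reference group level.
#' @slot table `data.frame` with columns `taxon`, `lfc` (natural-log fold
#'   change contrast vs reference), `se`, `p`, `q` (BH-adjusted).
#' @export
setClass("DAResult",
    representation(method = "character", contrast = "character",
                   reference = "character", table = "data.frame"))

setValidity("DAResult", function(object) {
    tb <- object@table
    need <- c("taxon", "lfc", "se", "p", "q")
    if (!all(need %in% names(tb)))
        return(paste("table must have columns", paste(need, collapse = ", ")))
    ok <- stats::complete.cases(tb[, c("p", "q")])
    if (any(tb$q[ok] + 1e-12 < tb$p[ok]))
        return("q must be >= p for every taxon")
    if (any(tb$q[ok] < 0 | tb$q[ok] > 1))
        return("q must lie in [0, 1]")
    if (any(!is.finite(tb$lfc)))
        return("lfc must be finite for all tested taxa")
    TRUE
})

#' Consensus over three differential-abundance models
#'
#' A taxon is flagged as a consensus hit iff it is significant (BH `q` below
#' `alpha`) in all three models and the three log fold changes share a sign.
#'
#' @slot contrast,reference the contrast shared by the three models.
#' @slot alpha significance threshold applied to each model's `q`.
#' @slot evidence long `data.frame`: one row per taxon x method with `lfc`,
#'   `se`, `p`, `q` (`NA` where a method did not test the taxon).
#' @slot summary `data.frame`: one row per taxon with `consensus` (logical)
#'   and `direction` (sign of the shared lfc; 0 when not consensus).
#' @export
setClass("DAConsensus",
    representation(contrast = "character", reference = "character",
                   alpha = "numeric", evidence = "data.frame",
                   summary = "data.frame"))

#' Definition of the log-ratio UC-CD index
#'
#' The index of a sample is the natural logarithm of the ratio of summed
#' relative abundances of taxa overrepresented in UC (vs CD) to those
#' underrepresented, with a pseudocount added to both sums.
#'
#' @slot upTaxa character, taxa overrepresented in the contrast group (UC).
#' @slot downTaxa character, taxa underrepresented in the contrast group.
#' @slot epsilon positive pseudocount on the relative-abundance scale.
#' @slot provenance list recording the contrast, reference and alpha that
#'   produced the taxon sets.
#' @export
setClass("IndexDefinition",
    representation(upTaxa = "character", downTaxa = "character",
                   epsilon = "numeric", provenance = "list"))

setValidity("IndexDefinition", function(object) {
    if (length(object@upTaxa) < 1 || length(object@downTaxa) < 1)
        return("both taxon sets must be non-empty")
    if (length(intersect(object@upTaxa, object@downTaxa)) > 0)
        return("upTaxa and downTaxa must be disjoint")
    if (length(object@epsilon) != 1 || object@epsilon <= 0)
        return("epsilon must be a single positive number")
    TRUE
})

#' Per-sample index scores
#'
#' @slot scores named numeric vector of per-sample index values.
#' @slot coverage fraction of index taxa present in the scored cohort's
#'   taxon universe.
#' @slot usable logical; `FALSE` when coverage is zero (scores are then
#'   uninformative and flagged as such).
#' @export
setClass("IndexScores",
    representation(scores = "numeric", coverage = "numeric",
                   usable = "logical"))

#' Monte Carlo cross-validation report for one feature set
#'
#' @slot featureSet label of the feature set (e.g. `"microbiome"`).
#' @slot aucs per-repeat test-set AUCs.
#' @slot attribution named numeric: mean absolute additive (SHAP)
#'   contribution per feature, averaged over repeats.
#' @slot seed,nRepeats,testFraction the split design; two reports are paired
#'   (repeat-by-repeat comparable) iff these match.
#' @slot n number of samples used.
#' @export
setClass("MCCVReport",
    representation(featureSet = "character", aucs = "numeric",
                   attribution = "numeric", seed = "integer",
                   nRepeats = "integer", testFraction = "numeric",
                   n = "integer"))

setValidity("MCCVReport", function(object) {
    if (length(object@aucs) < 1)
        return("at least one repeat is required")
    if (any(object@aucs < 0 | object@aucs > 1))
        return("AUCs must lie in [0, 1]")
    TRUE
})

#' Specification of a synthetic IBD cohort
#'
#' Parameters of the log-normal-multinomial generator in [generateCohort].
#' See that function for the generative model and the package vignette for
#' the rationale behind the defaults.
#'
#' @slot nPerGroup named integer vector, samples per diagnosis group.
#' @slot nTaxa number of genera.
#' @slot baseLogAbundance baseline log-scale composition (length `nTaxa`).
#' @slot dispersion log-normal sd of per-sample, per-taxon noise.
#' @slot depthMeanLog,depthSdLog log-normal parameters of library size.
#' @slot groupEffects,covariateEffects,batchEffects,severeEffects named lists
#'   mapping a group level / covariate / library to a numeric vector of
#'   per-taxon natural-log fold changes (sparse: named by taxon index or
#'   full-length vectors).
#' @slot pSevere named numeric, probability of a severe 1-year course per
#'   diagnosis group.
#' @slot nLibraries number of sequencing libraries (batches).
#' @export
setClass("CohortSpec",
    representation(nPerGroup = "integer", nTaxa = "integer",
                   baseLogAbundance = "numeric", dispersion = "numeric",
                   depthMeanLog = "numeric", depthSdLog = "numeric",
                   groupEffects = "list", covariateEffects = "list",
                   batchEffects = "list", severeEffects = "numeric",
                   pSevere = "numeric", nLibraries = "integer"))

setValidity("CohortSpec", function(object) {
    if (object@nTaxa < 2)
        return("at least two taxa are required")
    if (any(object@nPerGroup < 0) || sum(object@nPerGroup) < 1)
        return("nPerGroup must contain at least one sample")
    if (object@dispersion <= 0)
        return("dispersion must be positive")
    if (any(object@pSevere < 0 | object@pSevere > 1))
        return("pSevere entries must lie in [0, 1]")
    if (length(object@baseLogAbundance) != object@nTaxa)
        return("baseLogAbundance must have length nTaxa")
    TRUE
})
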