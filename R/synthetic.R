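#' Create a synthetic cohort specification
#'
#' Defines the generative model of [generateCohort]: a log-normal-multinomial
#' sampler in which diagnosis-group, covariate, sequencing-library (batch)
#' and severe-course effects compose additively on the log-abundance scale.
#' Defaults emulate the structure of a population-based adult IBD inception
#' cohort: group sizes follow the study population (658 UC, 324 CD, 36 IBD-U,
#' 26/41 suspected colon/small intestine, 144 symptomatic and 72 healthy
#' controls), 150 genera with a long-tailed baseline, heterogeneous
#' log-normal library sizes comfortably above the 10 000-read floor, and
#' severe-course probabilities of 17% (CD) and 9% (UC).
#'
#' Effect maps are named lists: names are diagnosis levels (or Montreal
#' location codes, enabling planted location gradients) for `groupEffects`,
#' covariate names for `covariateEffects`, library labels (`"L1"`...) for
#' `batchEffects`.  Each element is a numeric vector of natural-log fold
#' changes named by taxon id (sparse) or of length `nTaxa`.
#'
#' @param nPerGroup named integer vector of samples per diagnosis group.
#' @param nTaxa number of genera (default 150).
#' @param baseLogAbundance baseline log-scale composition; by default a
#'   fixed long-tailed (exponential) profile.
#' @param dispersion log-normal sd of per-sample taxon noise (default 1).
#' @param depthMeanLog,depthSdLog log-normal library-size parameters
#'   (default `log(30000)` and 0.35).
#' @param groupEffects,covariateEffects,batchEffects sparse effect maps, see
#'   Details.
#' @param severeEffects per-taxon log fold change applied to samples with a
#'   severe 1-year course.
#' @param pSevere named per-diagnosis probabilities of a severe course.
#' @param nLibraries number of sequencing libraries (default 8).
#' @return a [CohortSpec-class].
#' @export
CohortSpec <- function(nPerGroup = c(CD = 324, UC = 658, `IBD-U` = 36,
                                     suspected_colon = 26,
                                     suspected_small_intestine = 41,
                                     symptomatic_control = 144,
                                     healthy_control = 72),
                       nTaxa = 150,
                       baseLogAbundance = NULL,
                       dispersion = 1,
                       depthMeanLog = log(30000), depthSdLog = 0.35,
                       groupEffects = list(), covariateEffects = list(),
                       batchEffects = list(),
                       severeEffects = numeric(0),
                       pSevere = c(CD = 0.17, UC = 0.09, `IBD-U` = 0.12),
                       nLibraries = 8) {
    nTaxa <- assertCount(nTaxa, "nTaxa", min = 2)
    if (is.null(baseLogAbundance))
        baseLogAbundance <- withSeed(8675309,
            -sort(stats::rexp(nTaxa, rate = 1 / 2.5)))
    bad <- setdiff(names(nPerGroup), diagnosisLevels())
    if (length(bad) > 0)
        stop("unknown diagnosis group(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
    methods::new("CohortSpec",
        nPerGroup = stats::setNames(as.integer(nPerGroup), names(nPerGroup)),
        nTaxa = nTaxa,
        baseLogAbundance = as.numeric(baseLogAbundance),
        dispersion = dispersion,
        depthMeanLog = depthMeanLog, depthSdLog = depthSdLog,
        groupEffects = groupEffects, covariateEffects = covariateEffects,
        batchEffects = batchEffects,
        severeEffects = severeEffects,
        pSevere = pSevere,
        nLibraries = assertCount(nLibraries, "nLibraries", min = 1))
}

taxonIds <- function(nTaxa) sprintf("g%03d", seq_len(nTaxa))

# expand a sparse named effect vector to length nTaxa
expandEffect <- function(eff, taxa) {
    out <- numeric(length(taxa))
    names(out) <- taxa
    if (length(eff) == 0) return(out)
    if (is.null(names(eff)) || !any(nzchar(names(eff)))) {
        if (length(eff) != length(taxa))
            stop("unnamed effect vector must have length nTaxa",
                 call. = FALSE)
        return(stats::setNames(as.numeric(eff), taxa))
    }
    unknown <- setdiff(names(eff), taxa)
    if (length(unknown) > 0)
        stop("effect names not among taxa: ",
             paste(unknown, collapse = ", "), call. = FALSE)
    out[names(eff)] <- eff
    out
}

# standardized covariate value used when applying covariateEffects
standardizeCovariate <- function(name, value) {
    switch(name,
        age = (value - 40) / 10,
        bmi = (value - 25) / 4,
        sex = as.numeric(value == "male"),
        antibiotics = as.numeric(value),
        sampling_delay = (log1p(value) - 3),
        bss = (value - 4) / 1.5,
        as.numeric(value))
}

groupParam <- function(group, map, default) {
    if (group %in% names(map)) map[[group]] else default
}

drawMetadata <- function(spec) {
    groups <- rep(names(spec@nPerGroup), spec@nPerGroup)
    n <- length(groups)
    pf <- c(CD = 0.60, UC = 0.49)
    abx <- c(CD = 0.12, UC = 0.081, `IBD-U` = 0.11, suspected_colon = 0.19,
             suspected_small_intestine = 0.098, symptomatic_control = 0.12,
             healthy_control = 0)
    delayMed <- c(CD = 23, UC = 26, `IBD-U` = 15, suspected_colon = 20,
                  suspected_small_intestine = 18, symptomatic_control = 2,
                  healthy_control = 1)
    fcalMed <- c(CD = 320, UC = 205, `IBD-U` = 262, suspected_colon = 85,
                 suspected_small_intestine = 129, symptomatic_control = 47,
                 healthy_control = 40)
    crpMed <- c(CD = 5, UC = 3, `IBD-U` = 3, suspected_colon = 2,
                suspected_small_intestine = 3, symptomatic_control = 1,
                healthy_control = 1)
    md <- data.frame(
        sample_id = sprintf("S%04d", seq_len(n)),
        diagnosis = groups,
        stringsAsFactors = FALSE)
    md$age <- pmin(90, pmax(18, round(stats::rlnorm(n, log(39), 0.32))))
    md$sex <- ifelse(stats::runif(n) <
                     unname(vapply(groups, groupParam, 1, map = pf,
                                   default = 0.5)),
                     "female", "male")
    md$bmi <- round(pmin(45, pmax(15, stats::rnorm(n, 24.6, 4))), 1)
    md$antibiotics <- stats::runif(n) <
        unname(vapply(groups, groupParam, 1, map = abx, default = 0.1))
    # healthy controls were sequenced in a single library
    md$library <- ifelse(groups == "healthy_control", "L1",
                         paste0("L", sample.int(spec@nLibraries, n,
                                                replace = TRUE)))
    md$sampling_delay <- round(stats::rlnorm(
        n, log(unname(vapply(groups, groupParam, 1, map = delayMed,
                             default = 20))), 1))
    md$bss <- pmin(7L, pmax(1L, as.integer(round(stats::rnorm(n, 4, 1.3)))))
    md$f_calprotectin <- pmin(1801, pmax(29, round(stats::rlnorm(
        n, log(unname(vapply(groups, groupParam, 1, map = fcalMed,
                             default = 50))), 1.1))))
    md$crp <- round(stats::rlnorm(
        n, log(unname(vapply(groups, groupParam, 1, map = crpMed,
                             default = 1))), 0.9), 1)
    md$hemoglobin <- round(stats::rnorm(n, 13.5, 1.1), 1)
    md$ferritin <- round(stats::rlnorm(n, log(80), 0.8))
    md$transferrin <- round(stats::rnorm(n, 2.7, 0.4), 2)
    md$albumin <- round(stats::rnorm(n, 42, 3.5), 1)
    # Montreal classification: L-codes for CD, E-codes for UC
    md$montreal_location <- "none"
    isCD <- groups == "CD"
    md$montreal_location[isCD] <- sample(
        c("L1_ileal", "L2_colonic", "L3_ileocolonic"), sum(isCD),
        replace = TRUE, prob = c(0.30, 0.25, 0.45))
    isUC <- groups == "UC"
    md$montreal_location[isUC] <- sample(
        c("E1_proctitis", "E2_left_sided", "E3_total"), sum(isUC),
        replace = TRUE, prob = c(0.25, 0.35, 0.40))
    # severe 1-year course drawn first, then event records consistent with it
    pSev <- unname(vapply(groups, groupParam, 1, map = as.list(spec@pSevere),
                          default = 0))
    md$severe <- stats::runif(n) < pSev
    md <- cbind(md, drawEventRecords(md$severe, groups))
    # clinical disease-activity scores, weakly linked to the severe course
    md$mayo <- ifelse(isUC, pmin(3L, pmax(0L, as.integer(round(
        stats::rnorm(n, 1.6 + 0.4 * md$severe, 0.8))))), NA_integer_)
    md$sccai <- ifelse(isUC, pmin(12L, pmax(0L, as.integer(round(
        stats::rnorm(n, 4 + 1 * md$severe, 2))))), NA_integer_)
    md$hbi <- ifelse(isCD, pmin(16L, pmax(0L, as.integer(round(
        stats::rnorm(n, 5 + 1 * md$severe, 2.5))))), NA_integer_)
    md$sescd <- ifelse(isCD, pmin(30L, pmax(0L, as.integer(round(
        stats::rnorm(n, 8 + 1.5 * md$severe, 4))))), NA_integer_)
    md
}

drawEventRecords <- function(severe, groups) {
    n <- length(severe)
    ev <- data.frame(
        hospitalization_ibd = integer(n), surgery_ibd = logical(n),
        stoma = logical(n), corticosteroid_courses = integer(n),
        biologics_switched_for_failure = logical(n),
        fistula_abscess_stricture_new = logical(n),
        window = rep(12L, n))
    idx <- which(severe)
    for (i in idx) {
        isCD <- groups[i] == "CD"
        hosp <- stats::runif(1) < 0.65
        surg <- stats::runif(1) < 0.15
        stom <- stats::runif(1) < 0.05
        cort <- stats::runif(1) < 0.20
        biol <- stats::runif(1) < 0.10
        fist <- isCD && stats::runif(1) < 0.25
        if (!any(hosp, surg, stom, cort, biol, fist)) hosp <- TRUE
        ev$hospitalization_ibd[i] <- if (hosp) 1L + stats::rpois(1, 0.3)
                                     else 0L
        ev$surgery_ibd[i] <- surg
        ev$stoma[i] <- stom
        ev$corticosteroid_courses[i] <- if (cort) 3L + stats::rpois(1, 0.3)
                                        else sample(0:2, 1)
        ev$biologics_switched_for_failure[i] <- biol
        ev$fistula_abscess_stricture_new[i] <- fist
    }
    nonSevere <- which(!severe)
    ev$corticosteroid_courses[nonSevere] <-
        sample(0:2, length(nonSevere), replace = TRUE,
               prob = c(0.7, 0.2, 0.1))
    ev
}

#' Generate a synthetic cohort
#'
#' Per sample, the expected log abundance of each taxon is the baseline plus
#' the planted group, covariate, batch and (for severe-course samples)
#' severity effects; per-sample intensities are drawn log-normally with the
#' spec's dispersion, renormalized, and counts drawn multinomially at a
#' log-normal library size.  Covariates (age, sex, BMI, antibiotics,
#' library, sampling delay, Bristol stool scale, biochemistry, Montreal
#' location, event records and disease-activity scores) are drawn from
#' distributions loosely matched to published cohort summaries; see the
#' package vignette.
#'
#' @param spec a [CohortSpec-class].
#' @param seed integer seed; identical seeds give identical output.
#' @return a list with elements `experiment` (a
#'   [MicrobiomeExperiment-class] whose `colData` holds the metadata),
#'   and `truth` (every planted non-zero effect plus the per-sample severe
#'   indicator).
#' @examples
#' spec <- CohortSpec(nPerGroup = c(UC = 20, CD = 20), nTaxa = 40)
#' coh <- generateCohort(spec, seed = 1)
#' coh$experiment
#' @export
generateCohort <- function(spec, seed) {
    methods::validObject(spec)
    if (missing(seed)) stop("'seed' is required", call. = FALSE)
    withSeed(seed, {
        taxa <- taxonIds(spec@nTaxa)
        md <- drawMetadata(spec)
        n <- nrow(md)
        grpEff <- lapply(spec@groupEffects, expandEffect, taxa = taxa)
        covEff <- lapply(spec@covariateEffects, expandEffect, taxa = taxa)
        batEff <- lapply(spec@batchEffects, expandEffect, taxa = taxa)
        sevEff <- expandEffect(spec@severeEffects, taxa)
        counts <- matrix(0L, n, spec@nTaxa,
                         dimnames = list(md$sample_id, taxa))
        depths <- pmax(1, round(stats::rlnorm(n, spec@depthMeanLog,
                                              spec@depthSdLog)))
        for (i in seq_len(n)) {
            eta <- spec@baseLogAbundance
            for (key in names(grpEff))
                if (identical(md$diagnosis[i], key) ||
                    identical(md$montreal_location[i], key))
                    eta <- eta + grpEff[[key]]
            for (cv in names(covEff))
                eta <- eta + covEff[[cv]] *
                    standardizeCovariate(cv, md[[cv]][i])
            if (md$library[i] %in% names(batEff))
                eta <- eta + batEff[[md$library[i]]]
            if (md$severe[i]) eta <- eta + sevEff
            eta <- eta + stats::rnorm(spec@nTaxa, 0, spec@dispersion)
            w <- exp(eta - max(eta))
            counts[i, ] <- stats::rmultinom(1, depths[i], w / sum(w))[, 1]
        }
        truth <- list(
            groupEffects = lapply(grpEff, function(e) e[e != 0]),
            covariateEffects = lapply(covEff, function(e) e[e != 0]),
            batchEffects = lapply(batEff, function(e) e[e != 0]),
            severeEffects = sevEff[sevEff != 0],
            severe = stats::setNames(md$severe, md$sample_id))
        list(experiment = MicrobiomeExperiment(counts, metadata = md),
             truth = truth)
    })
}

#' Generate independent validation cohorts sharing planted effect directions
#'
#' Emulates cross-cohort transfer of the UC-CD index to external datasets
#' with imperfect taxon harmonization: each cohort keeps the planted UC/CD
#' effects but gets a cohort-specific, re-jittered baseline composition, and
#' the requested fraction of effect-carrying (index) taxa is removed from
#' its taxon universe.
#'
#' @param spec a [CohortSpec-class] with planted UC/CD `groupEffects`.
#' @param nCohorts number of cohorts (default 3).
#' @param harmonizationNoise fraction in `[0, 1]` of index taxa absent from
#'   each cohort (default 0).
#' @param seed integer seed.
#' @param baselineJitterSd sd of the per-cohort log-baseline perturbation.
#' @return list of cohorts, each as returned by [generateCohort].
#' @export
generateValidationCohorts <- function(spec, nCohorts = 3,
                                      harmonizationNoise = 0, seed,
                                      baselineJitterSd = 0.75) {
    if (!is.numeric(harmonizationNoise) || harmonizationNoise < 0 ||
        harmonizationNoise > 1)
        stop("'harmonizationNoise' must lie in [0, 1]", call. = FALSE)
    if (missing(seed)) stop("'seed' is required", call. = FALSE)
    taxa <- taxonIds(spec@nTaxa)
    idxTaxa <- unique(unlist(lapply(
        spec@groupEffects[intersect(names(spec@groupEffects), c("UC", "CD"))],
        function(e) names(e[e != 0]))))
    seeds <- deriveSeeds(seed, nCohorts, stream = 7L)
    lapply(seq_len(nCohorts), function(k) {
        coh <- withSeed(seeds[k], {
            sp <- spec
            sp@baseLogAbundance <- spec@baseLogAbundance +
                stats::rnorm(spec@nTaxa, 0, baselineJitterSd)
            drop <- character(0)
            if (harmonizationNoise > 0 && length(idxTaxa) > 0) {
                nDrop <- round(harmonizationNoise * length(idxTaxa))
                drop <- sample(idxTaxa, nDrop)
            }
            inner <- generateCohort(sp, seed = seeds[k] + 1L)
            if (length(drop) > 0) {
                keep <- setdiff(taxa, drop)
                inner$experiment <- inner$experiment[keep, ]
            }
            inner$droppedTaxa <- drop
            inner
        })
        coh
    })
}
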