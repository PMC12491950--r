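# Configuration-driven orchestration: ingest -> filter -> rarefy ->
# diversity -> consensus DA -> index -> outcome prediction, with one master
# seed fanned out per stage so adding a stage never perturbs earlier
# streams, and a JSON manifest recording outputs, checksums and warnings.

pipelineDefaults <- function() {
    list(min_depth = 10000, rarefaction_depth = 9503,
         da = list(group = "diagnosis", contrast = "UC", reference = "CD",
                   covariates = c("age", "sex", "antibiotics",
                                  "sampling_delay"),
                   random_intercept = "library", alpha = 0.05,
                   min_prevalence = 0.1),
         index = list(epsilon = 1e-6),
         mccv = list(diagnosis = "UC", n_repeats = 100,
                     test_fraction = 0.2,
                     feature_sets = c("microbiome", "biochemistry"),
                     include_clinical = FALSE),
         permutations = 999)
}

# deep-merge user config over defaults
mergeConfig <- function(defaults, user) {
    for (k in names(user)) {
        if (is.list(defaults[[k]]) && is.list(user[[k]]))
            defaults[[k]] <- mergeConfig(defaults[[k]], user[[k]])
        else defaults[[k]] <- user[[k]]
    }
    defaults
}

#' Read a pipeline run configuration
#'
#' YAML or JSON key-value file; unspecified settings fall back to package
#' defaults (minimum depth 10000, rarefaction depth 9503, UC-vs-CD DA with
#' alpha 0.05, index epsilon 1e-6, 100 MCCV repeats at test fraction 0.2).
#'
#' @param path config file (`.yaml`/`.yml`/`.json`).
#' @return config list.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
    user <- if (grepl("\\.json$", path))
        jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    cfg <- mergeConfig(pipelineDefaults(), user)
    if (is.null(cfg$seed)) stop("config must set 'seed'", call. = FALSE)
    cfg
}

stageError <- function(stage, e) {
    stop(structure(class = c("ibdmb_stage_error", "error", "condition"),
                   list(message = sprintf("[stage %s] %s", stage,
                                          conditionMessage(e)),
                        call = NULL, stage = stage,
                        code = paste0("E_", toupper(stage)))))
}

biochemistryColumns <- function() {
    c("f_calprotectin", "crp", "hemoglobin", "ferritin", "transferrin",
      "albumin")
}

clinicalColumns <- function() c("mayo", "sccai", "hbi", "sescd")

#' Run the full analysis pipeline
#'
#' Executes ingest (read or generate), minimum-depth filtering,
#' rarefaction, alpha/beta diversity with PERMANOVA and PERMDISP, the
#' three-model consensus DA, UC-CD index construction and scoring, and
#' Monte Carlo cross-validated severe-course prediction, writing every
#' intermediate artifact as TSV/JSON under `outdir` together with a run
#' manifest.  Reruns with the same config are bit-reproducible: all
#' randomness derives from the config's master seed.
#'
#' @param config a config list (see [readRunConfig]) or path to a config
#'   file.  Must contain either `input` (`counts`, `metadata` paths) or
#'   `generate` (arguments of [CohortSpec]) plus `seed` and `outdir`.
#' @return the run manifest (invisibly also written as
#'   `manifest.json`).
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- readRunConfig(config)
    config <- mergeConfig(pipelineDefaults(), config)
    if (is.null(config$seed)) stop("config must set 'seed'", call. = FALSE)
    if (is.null(config$outdir)) stop("config must set 'outdir'",
                                     call. = FALSE)
    outdir <- config$outdir
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    seeds <- deriveSeeds(config$seed, 7, stream = 1L)
    manifest <- list(package = "ibdmb",
                     version = as.character(utils::packageVersion("ibdmb")),
                     master_seed = config$seed, stages = list(),
                     warnings = character(0), checksums = list())
    warn <- function(w) {
        manifest$warnings <<- c(manifest$warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
    }
    note <- function(m) {
        manifest$warnings <<- c(manifest$warnings, conditionMessage(m))
        invokeRestart("muffleMessage")
    }
    addStage <- function(name, files, t0) {
        files <- files[file.exists(files)]
        sums <- as.list(tools::md5sum(files))
        names(sums) <- basename(files)
        manifest$stages[[length(manifest$stages) + 1]] <<-
            list(name = name, status = "complete",
                 outputs = basename(files),
                 seconds = round(as.numeric(Sys.time()) - t0, 2))
        manifest$checksums <<- c(manifest$checksums, sums)
    }
    runStage <- function(name, expr) {
        t0 <- as.numeric(Sys.time())
        res <- withCallingHandlers(
            tryCatch(expr, error = function(e) stageError(name, e)),
            warning = warn, message = note)
        list(value = res, t0 = t0)
    }

    ## 1: ingest
    st <- runStage("ingest", {
        if (!is.null(config$input)) {
            x <- readCountTable(config$input$counts,
                                format = if (!is.null(config$input$format))
                                    config$input$format else "tsv")
            md <- readSampleMetadata(config$input$metadata)
            x <- MicrobiomeExperiment(countMatrix(x), metadata = md)
        } else if (!is.null(config$generate)) {
            spec <- do.call(CohortSpec, config$generate)
            coh <- generateCohort(spec, seed = seeds[1])
            x <- coh$experiment
        } else stop("config needs 'input' or 'generate'")
        writeCountTable(x, file.path(outdir, "counts_raw.tsv"))
        writeSampleMetadata(sampleData(x)[
            , !vapply(sampleData(x), is.list, TRUE), drop = FALSE],
            file.path(outdir, "metadata.tsv"))
        x
    })
    x <- st$value
    addStage("ingest", file.path(outdir, c("counts_raw.tsv",
                                           "metadata.tsv")), st$t0)

    ## 2: filter
    st <- runStage("filter", {
        xf <- filterSamples(x, minDepth = config$min_depth)
        writeCountTable(xf, file.path(outdir, "counts_filtered.tsv"))
        xf
    })
    xf <- st$value
    addStage("filter", file.path(outdir, "counts_filtered.tsv"), st$t0)

    ## 3: rarefy
    st <- runStage("rarefy", {
        xr <- rarefy(xf, depth = config$rarefaction_depth, seed = seeds[2])
        writeCountTable(xr, file.path(outdir, "counts_rarefied.tsv"))
        xr
    })
    xr <- st$value
    addStage("rarefy", file.path(outdir, "counts_rarefied.tsv"), st$t0)

    ## 4: diversity
    st <- runStage("diversity", {
        al <- alphaDiversity(xr)
        utils::write.table(al, file.path(outdir, "alpha_diversity.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        md <- sampleData(xr)
        d <- suppressWarnings(brayCurtis(xr))
        grp <- factor(md$diagnosis)
        keep <- grp %in% names(table(grp))[table(grp) >= 2]
        dk <- stats::as.dist(as.matrix(d)[keep, keep])
        pa <- permanova(dk, droplevels(grp[keep]),
                        nPermutations = config$permutations,
                        seed = seeds[3])
        pd <- permdisp(dk, droplevels(grp[keep]),
                       nPermutations = config$permutations,
                       seed = seeds[3] + 1)
        tests <- data.frame(
            test = c("PERMANOVA", "PERMDISP"),
            statistic = c(pa@statistic, pd@statistic),
            r_squared = c(pa@rSquared, pd@rSquared),
            p = c(pa@p, pd@p),
            n_permutations = c(pa@nPermutations, pd@nPermutations))
        utils::write.table(tests, file.path(outdir, "diversity_tests.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        tests
    })
    addStage("diversity", file.path(outdir, c("alpha_diversity.tsv",
                                              "diversity_tests.tsv")),
             st$t0)

    ## 5: consensus DA
    st <- runStage("da_consensus", {
        dc <- config$da
        md <- sampleData(xf)
        sel <- md[[dc$group]] %in% c(dc$contrast, dc$reference)
        xs <- xf[, sel]
        args <- list(xs, group = dc$group, contrast = dc$contrast,
                     reference = dc$reference,
                     covariates = unlist(dc$covariates),
                     randomIntercept = dc$random_intercept,
                     minPrevalence = dc$min_prevalence)
        cons <- consensusDA(list(
            do.call(daBiasCorrectedLogLinear, args),
            do.call(daClrLinear, args),
            do.call(daTssLogLinear, args)), alpha = dc$alpha)
        utils::write.table(consensusTable(cons),
                           file.path(outdir, "da_consensus.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        cons
    })
    cons <- st$value
    addStage("da_consensus", file.path(outdir, "da_consensus.tsv"), st$t0)

    ## 6: index
    st <- runStage("index", {
        def <- buildIndex(cons, epsilon = config$index$epsilon)
        writeIndexDefinition(def, file.path(outdir,
                                            "index_definition.json"))
        sc <- applyIndex(def, xf)
        md <- sampleData(xf)
        tab <- data.frame(sample_id = names(sc@scores),
                          index = unname(sc@scores),
                          coverage = sc@coverage)
        utils::write.table(tab, file.path(outdir, "index_scores.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        sel <- md$diagnosis %in% c(config$da$contrast, config$da$reference)
        auc <- aucScore(sc@scores[sel], md$diagnosis[sel],
                        positive = config$da$contrast)
        list(def = def, scores = sc, auc = auc)
    })
    idx <- st$value
    addStage("index", file.path(outdir, c("index_definition.json",
                                          "index_scores.tsv")), st$t0)

    ## 7: outcome prediction
    st <- runStage("predict", {
        mc <- config$mccv
        md <- sampleData(xf)
        sel <- md$diagnosis %in% mc$diagnosis
        mds <- md[sel, , drop = FALSE]
        lab <- classifySevere(mds, mds$diagnosis)$severe
        rel <- toRelative(xf[, sel])
        covs <- mds[, intersect(c("age", "sex", "bmi", "antibiotics"),
                                names(mds)), drop = FALSE]
        sets <- list(microbiome = rel,
                     biochemistry = mds[, intersect(biochemistryColumns(),
                                                    names(mds)),
                                        drop = FALSE])
        if (isTRUE(mc$include_clinical))
            sets$clinical <- mds[, intersect(clinicalColumns(), names(mds)),
                                 drop = FALSE]
        sets[["microbiome+biochemistry"]] <-
            cbind(as.data.frame(rel), sets$biochemistry)
        sets <- sets[intersect(c(unlist(mc$feature_sets),
                                 "microbiome+biochemistry"), names(sets))]
        reports <- lapply(names(sets), function(nm)
            mccvPredict(sets[[nm]], lab, covariates = covs,
                        group = mds$library, featureSet = nm,
                        nRepeats = mc$n_repeats,
                        testFraction = mc$test_fraction, seed = seeds[5]))
        names(reports) <- names(sets)
        perRepeat <- do.call(rbind, lapply(reports, function(r)
            data.frame(feature_set = r@featureSet,
                       repeat_id = seq_along(r@aucs), auc = r@aucs)))
        utils::write.table(perRepeat, file.path(outdir, "mccv_aucs.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        summ <- lapply(reports, function(r) list(
            median_auc = stats::median(r@aucs),
            attribution_top10 = as.list(utils::head(
                sort(r@attribution, decreasing = TRUE), 10))))
        if (length(reports) >= 2) {
            cmp <- compareFeatureSets(reports[[1]], reports[[2]])
            summ$comparison <- list(
                sets = paste(names(reports)[1:2], collapse = " vs "),
                p = cmp$p, median_difference = cmp$medianDifference)
        }
        jsonlite::write_json(summ, file.path(outdir, "mccv_summary.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        reports
    })
    addStage("predict", file.path(outdir, c("mccv_aucs.tsv",
                                            "mccv_summary.json")), st$t0)

    manifest$index_auc <- idx$auc
    manifest$n_consensus_taxa <- length(consensusTaxa(cons))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
}
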