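#' Controlled vocabularies for sample metadata
#'
#' Diagnosis groups and Montreal disease-location codes accepted by
#' [validateSampleMetadata]. Montreal L-codes describe Crohn's disease
#' location (ileal, colonic, ileocolonic); E-codes describe ulcerative
#' colitis extent (proctitis, left-sided, extensive).
#'
#' @name vocabularies
NULL

diagnosisLevels <- function() {
    c("CD", "UC", "IBD-U", "suspected_colon", "suspected_small_intestine",
      "symptomatic_control", "healthy_control")
}

montrealLevels <- function() {
    c("L1_ileal", "L2_colonic", "L3_ileocolonic",
      "E1_proctitis", "E2_left_sided", "E3_total", "none")
}

#' Calprotectin assay recording range
#'
#' Fecal calprotectin ELISA results are recorded within 29-1801 ug/g;
#' values outside this range are clamped to the nearest limit at ingest.
#' @keywords internal
fcalRange <- function() c(29, 1801)

#' Construct a MicrobiomeExperiment
#'
#' @param counts numeric matrix of non-negative integer read counts with
#'   samples in rows and taxa in columns (matching the on-disk layout), with
#'   row and column names.  A taxa-by-samples matrix is accepted via
#'   `samplesAsRows = FALSE`.
#' @param metadata optional `data.frame` of per-sample covariates; either one
#'   row per sample in matching order, or carrying a `sample_id` column used
#'   to align.  Passed through [validateSampleMetadata].
#' @param taxonomy optional character vector of verbatim (possibly
#'   semicolon-delimited) taxonomy strings, one per taxon.
#' @param samplesAsRows orientation of `counts`.
#' @return A [MicrobiomeExperiment-class] object.
#' @examples
#' m <- matrix(c(5L, 0L, 1L, 2L, 0L, 7L), nrow = 3, byrow = TRUE,
#'             dimnames = list(paste0("S", 1:3), c("gA", "gB")))
#' me <- MicrobiomeExperiment(m)
#' sampleDepths(me)
#' @export
MicrobiomeExperiment <- function(counts, metadata = NULL, taxonomy = NULL,
                                 samplesAsRows = TRUE) {
    counts <- as.matrix(counts)
    if (samplesAsRows) counts <- t(counts)
    storage.mode(counts) <- "integer"
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("counts must carry sample and taxon names", call. = FALSE)
    if (anyDuplicated(colnames(counts)))
        stop("duplicate sample id: ",
             paste(unique(colnames(counts)[duplicated(colnames(counts))]),
                   collapse = ", "), call. = FALSE)
    if (anyDuplicated(rownames(counts)))
        stop("duplicate taxon id: ",
             paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                   collapse = ", "), call. = FALSE)
    if (is.null(taxonomy)) taxonomy <- rownames(counts)
    rd <- S4Vectors::DataFrame(
        taxonomy = as.character(taxonomy),
        genus_key = normalizeTaxonNames(taxonomy),
        row.names = rownames(counts))
    cd <- S4Vectors::DataFrame(row.names = colnames(counts))
    if (!is.null(metadata)) {
        metadata <- validateSampleMetadata(metadata)
        if ("sample_id" %in% names(metadata)) {
            miss <- setdiff(colnames(counts), metadata$sample_id)
            if (length(miss) > 0)
                stop("metadata missing samples: ",
                     paste(miss, collapse = ", "), call. = FALSE)
            metadata <- metadata[match(colnames(counts), metadata$sample_id), ,
                                 drop = FALSE]
        } else if (nrow(metadata) != ncol(counts)) {
            stop("metadata rows do not match samples", call. = FALSE)
        }
        cd <- S4Vectors::DataFrame(metadata, row.names = colnames(counts))
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), rowData = rd, colData = cd)
    obj <- new("MicrobiomeExperiment", se)
    nz <- sum(rowSums(counts) == 0)
    S4Vectors::metadata(obj)$n_zero_taxa <- nz
    if (nz > 0)
        message(nz, " taxa have all-zero counts")
    obj
}

#' Validate and normalize a sample metadata table
#'
#' Applies the package's ingest conventions: fecal calprotectin is clamped to
#' the assay recording range (29-1801 ug/g), Bristol stool scale values must
#' lie in 1-7, diagnosis and Montreal location must use the controlled
#' vocabularies, and Montreal codes must be consistent with diagnosis
#' (E-codes only for UC, L-codes only for CD).
#'
#' @param metadata a `data.frame`; recognised columns are validated, any
#'   others pass through untouched.
#' @return the validated `data.frame`.
#' @export
validateSampleMetadata <- function(metadata) {
    metadata <- as.data.frame(metadata)
    if ("diagnosis" %in% names(metadata)) {
        bad <- setdiff(unique(as.character(metadata$diagnosis)),
                       c(diagnosisLevels(), NA))
        if (length(bad) > 0)
            stop("unknown diagnosis value(s): ", paste(bad, collapse = ", "),
                 call. = FALSE)
    }
    if ("montreal_location" %in% names(metadata)) {
        loc <- as.character(metadata$montreal_location)
        bad <- setdiff(unique(loc), c(montrealLevels(), NA))
        if (length(bad) > 0)
            stop("unknown montreal_location value(s): ",
                 paste(bad, collapse = ", "), call. = FALSE)
        if ("diagnosis" %in% names(metadata)) {
            dg <- as.character(metadata$diagnosis)
            eBad <- !is.na(loc) & startsWith(loc, "E") & !is.na(dg) & dg != "UC"
            lBad <- !is.na(loc) & startsWith(loc, "L") & !is.na(dg) & dg != "CD"
            if (any(eBad | lBad))
                stop("montreal_location inconsistent with diagnosis for: ",
                     paste(utils::head(which(eBad | lBad), 5), collapse = ", "),
                     call. = FALSE)
        }
    }
    if ("bss" %in% names(metadata)) {
        b <- metadata$bss
        if (any(!is.na(b) & (b < 1 | b > 7)))
            stop("bss values must lie in 1-7", call. = FALSE)
    }
    if ("f_calprotectin" %in% names(metadata)) {
        r <- fcalRange()
        metadata$f_calprotectin <- pmin(pmax(metadata$f_calprotectin, r[1]),
                                        r[2])
    }
    metadata
}

#' @describeIn MicrobiomeExperiment total read count per sample.
#' @param x a `MicrobiomeExperiment`.
#' @export
sampleDepths <- function(x) {
    colSums(SummarizedExperiment::assay(x, "counts"))
}

#' Extract the count matrix
#'
#' @param x a [MicrobiomeExperiment-class].
#' @param samplesAsRows return samples-by-taxa (the package's analysis and
#'   on-disk orientation) when `TRUE`, taxa-by-samples otherwise.
#' @return integer matrix.
#' @export
countMatrix <- function(x, samplesAsRows = TRUE) {
    m <- SummarizedExperiment::assay(x, "counts")
    if (samplesAsRows) t(m) else m
}

#' Sample metadata as a data.frame
#' @param x a [MicrobiomeExperiment-class].
#' @export
sampleData <- function(x) {
    as.data.frame(SummarizedExperiment::colData(x))
}

setMethod("show", "MicrobiomeExperiment", function(object) {
    cat("MicrobiomeExperiment:", nrow(object), "taxa x", ncol(object),
        "samples\n")
    d <- sampleDepths(object)
    cat("  depth: median", stats::median(d), "range [", min(d), ",", max(d),
        "]\n")
    nz <- S4Vectors::metadata(object)$n_zero_taxa
    if (!is.null(nz) && nz > 0) cat("  all-zero taxa:", nz, "\n")
    cdn <- names(SummarizedExperiment::colData(object))
    if (length(cdn) > 0)
        cat("  metadata:", paste(utils::head(cdn, 8), collapse = ", "),
            if (length(cdn) > 8) "..." else "", "\n")
    invisible(object)
})
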