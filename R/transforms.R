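#' Normalize taxonomy labels to canonical genus keys
#'
#' Cross-cohort joins match taxa on the genus token: the last non-empty rank
#' of a semicolon-delimited lineage, stripped of QIIME-style rank prefixes
#' (`g__`), brackets, and SILVA group/clade decorations
#' (e.g. `"Lachnospiraceae ND3007 group"` and `"[Lachnospiraceae] ND3007"`
#' both map to `lachnospiraceae_nd3007`), lower-cased, with runs of
#' punctuation and whitespace collapsed to single underscores.
#'
#' @param labels character vector of taxon labels or lineage strings.
#' @return character vector of canonical keys, same length.
#' @examples
#' normalizeTaxonNames("d__Bacteria;f__Lachnospiraceae;g__Lachnospiraceae ND3007 group")
#' @export
normalizeTaxonNames <- function(labels) {
    labels <- as.character(labels)
    out <- vapply(labels, function(s) {
        parts <- strsplit(s, ";", fixed = TRUE)[[1]]
        parts <- trimws(parts)
        parts <- sub("^[a-zA-Z]__", "", parts)
        parts <- parts[nzchar(parts)]
        tok <- if (length(parts) == 0) s else parts[length(parts)]
        tok <- gsub("\\[|\\]", "", tok)
        tok <- tolower(trimws(tok))
        tok <- gsub("[[:space:][:punct:]]+", "_", tok)
        tok <- sub("_group$", "", tok)
        tok <- sub("^_+|_+$", "", tok)
        tok
    }, character(1), USE.NAMES = FALSE)
    out
}

#' Drop samples below a minimum sequencing depth
#'
#' Mirrors the study-design quality gate that samples yielding fewer than
#' 10 000 reads are not carried into analysis.
#'
#' @param x a [MicrobiomeExperiment-class].
#' @param minDepth minimum total read count (inclusive); default 10000.
#' @return the filtered object; removed sample ids are reported via
#'   `message()`.
#' @export
filterSamples <- function(x, minDepth = 10000) {
    minDepth <- assertCount(minDepth, "minDepth")
    d <- sampleDepths(x)
    keep <- d >= minDepth
    if (!any(keep))
        stop("empty result: all ", length(d), " samples fall below depth ",
             minDepth, call. = FALSE)
    if (any(!keep))
        message("filterSamples: removed ", sum(!keep), " sample(s): ",
                paste(utils::head(colnames(x)[!keep], 10), collapse = ", "))
    x[, keep]
}

#' Rarefy to even depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric) to a common depth.  Samples whose total falls below the
#' target depth are dropped with a message, never upsampled.
#'
#' @param x a [MicrobiomeExperiment-class].
#' @param depth target depth; default 9503.
#' @param seed required integer seed; identical seeds give bit-identical
#'   output.
#' @return rarefied [MicrobiomeExperiment-class]; every retained sample's
#'   total equals `depth` exactly.
#' @export
rarefy <- function(x, depth = 9503, seed) {
    depth <- assertCount(depth, "depth", min = 1)
    if (missing(seed))
        stop("'seed' is required for rarefaction", call. = FALSE)
    d <- sampleDepths(x)
    keep <- d >= depth
    if (!any(keep))
        stop("empty result: no sample reaches rarefaction depth ", depth,
             call. = FALSE)
    if (any(!keep))
        message("rarefy: dropped ", sum(!keep),
                " sample(s) below depth ", depth, ": ",
                paste(utils::head(colnames(x)[!keep], 10), collapse = ", "))
    x <- x[, keep]
    m <- SummarizedExperiment::assay(x, "counts")  # taxa x samples
    out <- withSeed(seed, {
        apply(m, 2, function(cnt) {
            tot <- sum(cnt)
            if (tot == depth) return(cnt)
            picked <- sample.int(tot, depth)
            # map read indices back to taxa via cumulative counts
            tabulate(findInterval(picked - 1L, cumsum(cnt)) + 1L,
                     nbins = length(cnt))
        })
    })
    out <- matrix(out, nrow = nrow(m),
                  dimnames = list(rownames(m), colnames(m)))
    storage.mode(out) <- "integer"
    y <- replaceCounts(x, out)
    y
}

# swap the counts assay, keeping row/colData
replaceCounts <- function(x, counts) {
    SummarizedExperiment::assay(x, "counts") <- counts
    methods::validObject(x)
    x
}

#' Total-sum scaling to relative abundances
#'
#' @param x a [MicrobiomeExperiment-class] or samples-by-taxa count matrix.
#' @return samples-by-taxa matrix whose rows sum to 1.
#' @export
toRelative <- function(x) {
    m <- if (methods::is(x, "MicrobiomeExperiment"))
        countMatrix(x, samplesAsRows = TRUE) else as.matrix(x)
    tot <- rowSums(m)
    if (any(tot == 0))
        stop("zero-total sample(s): ",
             paste(utils::head(rownames(m)[tot == 0], 10), collapse = ", "),
             call. = FALSE)
    m / tot
}

#' Centered log-ratio transform
#'
#' Per sample, `log(count + pseudocount)` centered by the sample's mean log,
#' removing the compositional constraint; every output row sums to zero.
#'
#' @param x a [MicrobiomeExperiment-class] or samples-by-taxa count matrix.
#' @param pseudocount positive offset added before taking logs; default 0.5.
#' @return samples-by-taxa real matrix.
#' @export
clrTransform <- function(x, pseudocount = 0.5) {
    if (!is.numeric(pseudocount) || length(pseudocount) != 1 ||
        pseudocount <= 0)
        stop("'pseudocount' must be a single positive number", call. = FALSE)
    m <- if (methods::is(x, "MicrobiomeExperiment"))
        countMatrix(x, samplesAsRows = TRUE) else as.matrix(x)
    lg <- log(m + pseudocount)
    lg - rowMeans(lg)
}
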