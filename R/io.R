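#' Read a genus-level feature table
#'
#' Reads a samples-by-taxa count table.  The TSV layout is: first column
#' `sample_id`, header row of taxon labels (verbatim, possibly
#' semicolon-delimited lineages), integer cells; lines starting with `#` are
#' ignored.  BIOM tables (taxa-by-samples, as conventional for that format)
#' are read through the `biomformat` package and transposed.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom"`.
#' @return a [MicrobiomeExperiment-class] preserving the input sample and
#'   taxon ordering.
#' @export
readCountTable <- function(path, format = c("tsv", "biom")) {
    format <- match.arg(format)
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    if (format == "biom") {
        if (!requireNamespace("biomformat", quietly = TRUE))
            stop("reading BIOM requires the 'biomformat' package",
                 call. = FALSE)
        b <- biomformat::read_biom(path)
        m <- as(biomformat::biom_data(b), "matrix")  # taxa x samples
        return(MicrobiomeExperiment(m, samplesAsRows = FALSE))
    }
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
    if (length(lines) < 2)
        stop("format error: empty or headerless count table: ", path,
             call. = FALSE)
    tab <- utils::read.table(text = lines, sep = "\t", header = TRUE,
                             check.names = FALSE, quote = "",
                             comment.char = "", stringsAsFactors = FALSE)
    ids <- as.character(tab[[1]])
    if (anyDuplicated(ids))
        stop("duplicate sample id: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "),
             call. = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(m))
        stop("format error: non-numeric count entries in ", path,
             call. = FALSE)
    if (any(is.na(m)) || any(m < 0) || any(abs(m - round(m)) > 1e-8))
        stop("format error: counts must be non-negative integers",
             call. = FALSE)
    rownames(m) <- ids
    MicrobiomeExperiment(m, samplesAsRows = TRUE)
}

#' Write a count table as TSV
#'
#' Samples-as-rows layout with a header comment declaring the orientation.
#'
#' @param x a [MicrobiomeExperiment-class].
#' @param path output path.
#' @export
writeCountTable <- function(x, path) {
    m <- countMatrix(x, samplesAsRows = TRUE)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# orientation: samples-as-rows", con)
    writeLines(paste(c("sample_id", colnames(m)), collapse = "\t"), con)
    utils::write.table(m, con, sep = "\t", quote = FALSE, col.names = FALSE,
                       row.names = TRUE)
    invisible(path)
}

#' Read a sample metadata table
#'
#' One row per sample; missing values may be empty strings or `"NA"`.
#' Controlled vocabularies and ingest conventions (calprotectin clamping,
#' Bristol stool scale range, Montreal/diagnosis consistency) are enforced
#' by [validateSampleMetadata].
#'
#' @param path TSV file with a `sample_id` column.
#' @return validated `data.frame`.
#' @export
readSampleMetadata <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    md <- utils::read.table(path, sep = "\t", header = TRUE,
                            na.strings = c("", "NA"), quote = "",
                            comment.char = "#", stringsAsFactors = FALSE,
                            check.names = FALSE)
    if (!"sample_id" %in% names(md))
        stop("metadata must contain a 'sample_id' column", call. = FALSE)
    if (anyDuplicated(md$sample_id))
        stop("duplicate sample id in metadata", call. = FALSE)
    validateSampleMetadata(md)
}

#' Write sample metadata as TSV
#' @param metadata a `data.frame` with `sample_id`.
#' @param path output path.
#' @export
writeSampleMetadata <- function(metadata, path) {
    utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}
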