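#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: `q_(i) = min_{j >= i}
#' p_(j) * m / j`, capped at 1.  `NA` p-values propagate as `NA` and are
#' excluded from `m`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return vector of q-values, same length and order.
#' @export
bhAdjust <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]", call. = FALSE)
    q <- rep(NA_real_, length(p))
    ok <- !is.na(p)
    q[ok] <- stats::p.adjust(p[ok], method = "BH")
    q
}

#' Three-model consensus differential abundance
#'
#' Applies the stringent consensus rule: a taxon is reported as
#' differentially abundant only when its BH-adjusted q-value is below
#' `alpha` in all three models *and* the three log fold changes share a
#' sign.  Taxa untested by any model (e.g. prevalence-filtered there) are
#' never consensus; mismatched taxon universes are unioned with untested
#' entries treated as non-significant.
#'
#' @param results list of three [DAResult-class] objects for the same
#'   contrast, one per method.
#' @param alpha per-method significance threshold (default 0.05).
#' @return a [DAConsensus-class].
#' @examples
#' ## see consensusTable() for turning the result into a tidy table
#' @export
consensusDA <- function(results, alpha = 0.05) {
    if (length(results) != 3 ||
        !all(vapply(results, methods::is, TRUE, "DAResult")))
        stop("'results' must be a list of three DAResult objects",
             call. = FALSE)
    methodsUsed <- vapply(results, function(r) r@method, "")
    if (anyDuplicated(methodsUsed))
        stop("the three results must come from distinct methods",
             call. = FALSE)
    ctr <- unique(vapply(results, function(r) r@contrast, ""))
    ref <- unique(vapply(results, function(r) r@reference, ""))
    if (length(ctr) != 1 || length(ref) != 1)
        stop("all three results must cover the same contrast", call. = FALSE)
    universes <- lapply(results, function(r) r@table$taxon)
    taxa <- sort(unique(unlist(universes)))
    if (any(vapply(universes, function(u) length(setdiff(taxa, u)) > 0,
                   TRUE)))
        message("consensusDA: taxon universes differ across methods; ",
                "untested taxa treated as non-significant")
    ev <- do.call(rbind, lapply(results, function(r) {
        tb <- r@table[match(taxa, r@table$taxon), ]
        data.frame(taxon = taxa, method = r@method, lfc = tb$lfc,
                   se = tb$se, p = tb$p, q = tb$q, row.names = NULL)
    }))
    qMat <- matrix(ev$q, nrow = length(taxa),
                   dimnames = list(taxa, methodsUsed))
    lfcMat <- matrix(ev$lfc, nrow = length(taxa))
    sig <- !is.na(qMat) & qMat < alpha
    signs <- sign(lfcMat)
    concordant <- apply(signs, 1, function(s)
        !any(is.na(s)) && length(unique(s)) == 1 && s[1] != 0)
    consensus <- rowSums(sig) == 3 & concordant
    discord <- rowSums(sig) == 3 & !concordant
    if (any(discord))
        message("consensusDA: discordant sign at q < ", alpha, " for: ",
                paste(taxa[discord], collapse = ", "))
    direction <- ifelse(consensus, signs[, 1], 0)
    summary <- data.frame(taxon = taxa, consensus = unname(consensus),
                          direction = as.integer(direction),
                          row.names = NULL)
    methods::new("DAConsensus", contrast = ctr, reference = ref,
                 alpha = alpha, evidence = ev, summary = summary)
}

#' Tidy per-taxon consensus table
#'
#' One row per taxon x method with the consensus flag and direction joined
#' on, matching the package's result TSV layout.
#'
#' @param x a [DAConsensus-class].
#' @return `data.frame` with columns `taxon`, `method`, `lfc`, `se`, `p`,
#'   `q`, `consensus`, `direction`.
#' @export
consensusTable <- function(x) {
    merge(x@evidence, x@summary, by = "taxon", sort = FALSE)
}

#' Taxa passing the consensus rule
#' @param x a [DAConsensus-class].
#' @return character vector.
#' @export
consensusTaxa <- function(x) {
    x@summary$taxon[x@summary$consensus]
}

setMethod("show", "DAConsensus", function(object) {
    cat("DAConsensus: ", object@contrast, " vs ", object@reference,
        " (reference), alpha = ", object@alpha, "\n", sep = "")
    hits <- consensusTaxa(object)
    cat("  ", nrow(object@summary), " taxa assessed, ", length(hits),
        " consensus hits\n", sep = "")
    if (length(hits) > 0)
        cat("  hits:", paste(utils::head(hits, 10), collapse = ", "),
            if (length(hits) > 10) "..." else "", "\n")
    invisible(object)
})
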