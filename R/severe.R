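#' Classify the composite severe-disease-course endpoint
#'
#' One-year composite endpoint reflecting difficult-to-control inflammation
#' or complications.  A course is severe when any criterion is met within
#' the first 12 months:
#' * IBD-related hospitalization (any),
#' * IBD-related surgery,
#' * stoma formation,
#' * more than 2 corticosteroid courses (strictly greater: exactly 2 is
#'   not severe),
#' * a second biologic started because the first failed,
#' * and, in CD only, new findings of (or surgery for) fistulas, abscesses
#'   or strictures.
#'
#' @param events `data.frame` of event records with columns
#'   `hospitalization_ibd` (count), `surgery_ibd`, `stoma` (logical),
#'   `corticosteroid_courses` (count), `biologics_switched_for_failure`
#'   (logical), `fistula_abscess_stricture_new` (logical), and optionally
#'   `window` (must be 12 months) and `sample_id`.
#' @param diagnosis character vector (recycled if length 1); must be
#'   `"UC"`, `"CD"` or `"IBD-U"`.  Non-CD diagnoses use the UC criteria.
#' @return `data.frame` with `sample_id`, `severe` (logical) and
#'   `triggering_criteria` (list column; empty iff not severe).
#' @export
classifySevere <- function(events, diagnosis) {
    events <- as.data.frame(events)
    n <- nrow(events)
    if (length(diagnosis) == 1) diagnosis <- rep(diagnosis, n)
    if (length(diagnosis) != n)
        stop("'diagnosis' must match the number of event records",
             call. = FALSE)
    bad <- setdiff(unique(diagnosis), c("UC", "CD", "IBD-U"))
    if (length(bad) > 0)
        stop("severe-course classification is defined for UC, CD and ",
             "IBD-U only; got: ", paste(bad, collapse = ", "),
             call. = FALSE)
    need <- c("hospitalization_ibd", "surgery_ibd", "stoma",
              "corticosteroid_courses", "biologics_switched_for_failure",
              "fistula_abscess_stricture_new")
    miss <- setdiff(need, names(events))
    if (length(miss) > 0)
        stop("event records missing column(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
    if ("window" %in% names(events) &&
        any(stats::na.omit(events$window) != 12))
        stop("event windows must be 12 months", call. = FALSE)
    if (any(events$hospitalization_ibd < 0, na.rm = TRUE) ||
        any(events$corticosteroid_courses < 0, na.rm = TRUE))
        stop("event counts must be non-negative", call. = FALSE)
    trig <- lapply(seq_len(n), function(i) {
        t <- character(0)
        if (isTRUE(events$hospitalization_ibd[i] >= 1))
            t <- c(t, "hospitalization")
        if (isTRUE(events$surgery_ibd[i])) t <- c(t, "surgery")
        if (isTRUE(events$stoma[i])) t <- c(t, "stoma")
        if (isTRUE(events$corticosteroid_courses[i] > 2))
            t <- c(t, "corticosteroids_gt2")
        if (isTRUE(events$biologics_switched_for_failure[i]))
            t <- c(t, "second_biologic_after_failure")
        if (diagnosis[i] == "CD" &&
            isTRUE(events$fistula_abscess_stricture_new[i]))
            t <- c(t, "fistula_abscess_stricture")
        t
    })
    ids <- if ("sample_id" %in% names(events)) events$sample_id
           else as.character(seq_len(n))
    out <- data.frame(sample_id = ids,
                      severe = lengths(trig) > 0)
    out$triggering_criteria <- trig
    out
}
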