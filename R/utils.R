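# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.  Seeds are explicit arguments throughout the package; nothing
# relies on the global stream.
withSeed <- function(seed, expr) {
    if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
        stop("'seed' must be a single integer", call. = FALSE)
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv()),
            add = TRUE)
    }
    set.seed(as.integer(seed))
    expr
}

# Derive a stream of child seeds from one master seed.  Uses a fixed affine
# scheme so adding a consumer never perturbs earlier consumers' streams.
deriveSeeds <- function(seed, n, stream = 0L) {
    (as.integer(seed) + 100003L * as.integer(stream) + 17L * seq_len(n)) %%
        .Machine$integer.max
}

assertFlag <- function(x, name) {
    if (!is.logical(x) || length(x) != 1 || is.na(x))
        stop(sprintf("'%s' must be TRUE or FALSE", name), call. = FALSE)
    x
}

assertCount <- function(x, name, min = 0) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
        abs(x - round(x)) > 1e-8)
        stop(sprintf("'%s' must be a single integer >= %s", name, min),
             call. = FALSE)
    as.integer(round(x))
}
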