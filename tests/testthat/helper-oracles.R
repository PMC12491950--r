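# Independent oracles and shared fixtures for the test suite.  The oracles
# are deliberately naive (brute force / direct-definition) so they stay
# independent of the implementation paths they check.

# Brute-force Benjamini-Hochberg step-up: q_(i) = min over j with
# p_(j) >= p_(i) of p_(j) * m / j, capped at 1.
bruteForceBH <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    q <- numeric(m)
    for (i in seq_len(m)) {
        cand <- ps[i:m] * m / (i:m)
        q[i] <- min(1, min(cand))
    }
    out <- numeric(m)
    out[o] <- q
    out
}

# Brute-force AUC: loop over every positive-negative pair, ties count 1/2.
bruteForceAUC <- function(scores, pos) {
    sp <- scores[pos]
    sn <- scores[!pos]
    tot <- 0
    for (a in sp) for (b in sn)
        tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(sp) * length(sn))
}

# From-scratch PERMANOVA pseudo-F via the within-group sum-of-squares
# identity, and its exhaustive p over all assignments of labels.
permanovaOracleF <- function(D2, lab) {
    n <- nrow(D2)
    groups <- unique(lab)
    ssw <- 0
    for (lv in groups) {
        i <- which(lab == lv)
        ssw <- ssw + sum(D2[i, i][upper.tri(D2[i, i])]) / length(i)
    }
    sst <- sum(D2[upper.tri(D2)]) / n
    a <- length(groups)
    ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

permanovaOracleExhaustive <- function(d, lab) {
    D2 <- as.matrix(d)^2
    n <- nrow(D2)
    F0 <- permanovaOracleF(D2, lab)
    idx <- which(lab == unique(lab)[1])
    combs <- utils::combn(n, length(idx))
    Fs <- apply(combs, 2, function(i) {
        l2 <- rep("B", n)
        l2[i] <- "A"
        permanovaOracleF(D2, l2)
    })
    list(F = F0, p = mean(Fs >= F0 - 1e-12))
}

# tiny labelled count matrix (samples x taxa)
tinyCounts <- function() {
    matrix(c(5L, 0L, 1L, 2L, 0L, 7L), nrow = 3, byrow = TRUE,
           dimnames = list(paste0("S", 1:3), c("gA", "gB")))
}

# balanced UC/CD cohort with optional planted group effects
makeCohort <- function(seed, n = 100, nTaxa = 150, effects = list(),
                       ...) {
    spec <- CohortSpec(nPerGroup = c(UC = n, CD = n), nTaxa = nTaxa,
                       groupEffects = effects, ...)
    suppressMessages(generateCohort(spec, seed = seed))
}

# common fast DA arguments (no covariates / random intercept)
runThreeDA <- function(x, ...) {
    args <- list(x, contrast = "UC", reference = "CD",
                 covariates = NULL, randomIntercept = NULL, ...)
    list(do.call(daBiasCorrectedLogLinear, args),
         do.call(daClrLinear, args),
         do.call(daTssLogLinear, args))
}

# committed planted-scenario taxa (mid-abundance genera)
plantedUp <- function() sprintf("g%03d", c(40, 45, 50, 55, 60))
plantedDown <- function() sprintf("g%03d", c(65, 70, 75, 80, 85))
plantedIndexEffects <- function(lfc = log(4)) {
    c(stats::setNames(rep(lfc, 5), plantedUp()),
      stats::setNames(rep(-lfc, 5), plantedDown()))
}
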