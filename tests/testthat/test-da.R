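test_that("BH adjustment matches the brute-force step-up oracle", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)),
                 c(0.04, 0.04, 0.04, 0.04))
    expect_equal(bhAdjust(0.05), 0.05)
    expect_equal(bhAdjust(c(0.001, 0.9)), c(0.002, 0.9))
    set.seed(17)
    for (i in 1:50) {
        p <- runif(sample(1:40, 1))
        expect_equal(bhAdjust(p), bruteForceBH(p), tolerance = 1e-12)
    }
    q <- bhAdjust(c(0.01, NA, 0.5))
    expect_true(is.na(q[2]))
    expect_equal(q[c(1, 3)], bruteForceBH(c(0.01, 0.5)))
    expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("self-contrast gives identically zero fold changes", {
    coh <- makeCohort(5, n = 10, nTaxa = 30)
    for (fn in list(daBiasCorrectedLogLinear, daClrLinear,
                    daTssLogLinear)) {
        r <- fn(coh$experiment, contrast = "UC", reference = "UC",
                covariates = NULL, randomIntercept = NULL)
        expect_true(all(r@table$lfc == 0))
        expect_true(all(r@table$q == 1))
    }
})

test_that("a constant taxon at equal depths is a clean null", {
    set.seed(2)
    m <- matrix(rpois(40 * 20, 30), 40)
    m[, 5] <- 50L
    depths <- rowSums(m)
    # equalize depths by adjusting a filler taxon
    m[, 20] <- m[, 20] + (max(depths) - depths)
    colnames(m) <- sprintf("g%02d", 1:20)
    rownames(m) <- sprintf("S%02d", 1:40)
    md <- data.frame(diagnosis = rep(c("UC", "CD"), each = 20))
    r <- daClrLinear(m, md, contrast = "UC", reference = "CD",
                     covariates = NULL, randomIntercept = NULL)
    expect_lt(abs(r@table$lfc[r@table$taxon == "g05"]), 0.15)
    expect_gt(r@table$p[r@table$taxon == "g05"], 0.05)
})

test_that("all three models recover a planted fold change", {
    coh <- makeCohort(101, n = 200, effects = list(UC = c(g050 = log(4))))
    for (r in runThreeDA(coh$experiment)) {
        row <- r@table[r@table$taxon == "g050", ]
        expect_equal(row$lfc, log(4), tolerance = 0.3)
        expect_lt(row$q, 0.05)
    }
})

test_that("q-values dominate p-values and results keep taxon order", {
    coh <- makeCohort(6, n = 40, nTaxa = 60)
    r <- daTssLogLinear(coh$experiment, contrast = "UC",
                        reference = "CD", covariates = NULL,
                        randomIntercept = NULL)
    expect_true(all(r@table$q >= r@table$p - 1e-12))
    expect_true(all(r@table$q <= 1))
    expect_true(all(is.finite(r@table$lfc)))
})

test_that("prevalence filtering controls which taxa are tested", {
    set.seed(3)
    m <- matrix(rpois(30 * 10, 40), 30)
    m[, 10] <- 0L
    m[1, 10] <- 2L  # 1/30 prevalence
    colnames(m) <- sprintf("g%02d", 1:10)
    rownames(m) <- sprintf("S%02d", 1:30)
    md <- data.frame(diagnosis = rep(c("UC", "CD"), each = 15))
    r <- daClrLinear(m, md, contrast = "UC", reference = "CD",
                     covariates = NULL, randomIntercept = NULL,
                     minPrevalence = 0.1)
    expect_false("g10" %in% r@table$taxon)
    r2 <- daClrLinear(m, md, contrast = "UC", reference = "CD",
                      covariates = NULL, randomIntercept = NULL,
                      minPrevalence = 0)
    expect_true("g10" %in% r2@table$taxon)
})

test_that("all-zero samples are rejected", {
    m <- matrix(c(0L, 0L, 5L, 3L), 2, byrow = TRUE,
                dimnames = list(c("S1", "S2"), c("a", "b")))
    md <- data.frame(diagnosis = c("UC", "CD"))
    expect_error(daTssLogLinear(m, md, contrast = "UC", reference = "CD",
                                covariates = NULL,
                                randomIntercept = NULL),
                 "all-zero")
})

test_that("consensus rule: q threshold in all three plus sign agreement", {
    mk <- function(method, q, lfc) {
        methods::new("DAResult", method = method, contrast = "UC",
                     reference = "CD",
                     table = data.frame(taxon = c("A", "B", "C"),
                                        lfc = lfc, se = 0.1,
                                        p = q / 2, q = q))
    }
    r1 <- mk("bias_corrected_loglinear", c(0.01, 0.01, 0.20),
             c(1, 1, -1))
    r2 <- mk("clr_linear", c(0.04, 0.01, 0.30), c(1, 1, -1))
    r3 <- mk("tss_log_linear", c(0.049, 0.06, 0.40), c(1, -1, -1))
    cons <- consensusDA(list(r1, r2, r3))
    sm <- cons@summary
    expect_true(sm$consensus[sm$taxon == "A"])     # all q < .05, signs +
    expect_false(sm$consensus[sm$taxon == "B"])    # one q = .06
    expect_false(sm$consensus[sm$taxon == "C"])    # not significant
    expect_equal(sm$direction[sm$taxon == "A"], 1)
    # discordant signs at q < alpha are rejected and logged
    r3b <- mk("tss_log_linear", c(0.01, 0.01, 0.4), c(-1, -1, -1))
    expect_message(cons2 <- consensusDA(list(r1, r2, r3b)), "discordant")
    expect_false(cons2@summary$consensus[cons2@summary$taxon == "A"])
})

test_that("consensus unions mismatched taxon universes as non-significant", {
    mk <- function(method, taxa) {
        methods::new("DAResult", method = method, contrast = "UC",
                     reference = "CD",
                     table = data.frame(taxon = taxa, lfc = 1, se = 0.1,
                                        p = 0.001, q = 0.004))
    }
    r1 <- mk("bias_corrected_loglinear", c("A", "B"))
    r2 <- mk("clr_linear", c("A", "B"))
    r3 <- mk("tss_log_linear", "A")
    expect_message(cons <- consensusDA(list(r1, r2, r3)), "universes")
    expect_true(cons@summary$consensus[cons@summary$taxon == "A"])
    expect_false(cons@summary$consensus[cons@summary$taxon == "B"])
})

test_that("consensus is invariant to taxon and sample permutations", {
    eff <- list(UC = c(g040 = log(4), g060 = -log(4)))
    coh <- makeCohort(31, n = 80, nTaxa = 60, effects = eff)
    x <- coh$experiment
    hits1 <- consensusTaxa(suppressMessages(
        consensusDA(runThreeDA(x))))
    set.seed(1)
    xp <- x[sample(nrow(x)), sample(ncol(x))]
    hits2 <- consensusTaxa(suppressMessages(
        consensusDA(runThreeDA(xp))))
    expect_setequal(hits1, hits2)
})

test_that("a library random intercept absorbs batch confounding", {
    bat <- list(L1 = stats::setNames(rep(1.2, 8),
                                     sprintf("g%03d", seq(30, 65, 5))))
    spec <- CohortSpec(nPerGroup = c(UC = 90, healthy_control = 50),
                       nTaxa = 70, batchEffects = bat, nLibraries = 4)
    fp <- vapply(1:3, function(s) {
        coh <- suppressMessages(generateCohort(spec, seed = 520 + s))
        x <- coh$experiment
        bt <- names(bat$L1)
        withRI <- daClrLinear(x, contrast = "UC",
                              reference = "healthy_control",
                              covariates = NULL,
                              randomIntercept = "library")
        noRI <- daClrLinear(x, contrast = "UC",
                            reference = "healthy_control",
                            covariates = NULL, randomIntercept = NULL)
        c(sum(withRI@table$q < 0.05 & withRI@table$taxon %in% bt),
          sum(noRI@table$q < 0.05 & noRI@table$taxon %in% bt))
    }, numeric(2))
    expect_lte(sum(fp[1, ]), sum(fp[2, ]))
    expect_gt(sum(fp[2, ]), 0)
})

test_that("two-level batches fall back to a fixed library term", {
    coh <- makeCohort(3, n = 30, nTaxa = 40, nLibraries = 2)
    r <- daClrLinear(coh$experiment, contrast = "UC", reference = "CD",
                     covariates = NULL, randomIntercept = "library")
    expect_s4_class(r, "DAResult")
    expect_equal(nrow(r@table), sum(colMeans(
        countMatrix(coh$experiment) > 0) >= 0.1))
})
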