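test_that("index construction splits consensus taxa by direction", {
    mk <- function(method, q, lfc) {
        methods::new("DAResult", method = method, contrast = "UC",
                     reference = "CD",
                     table = data.frame(taxon = c("A", "B", "C"),
                                        lfc = lfc, se = 0.1, p = q / 2,
                                        q = q))
    }
    cons <- consensusDA(list(
        mk("bias_corrected_loglinear", c(0.01, 0.01, 0.01), c(1, 2, -1)),
        mk("clr_linear", c(0.01, 0.01, 0.01), c(1, 1, -2)),
        mk("tss_log_linear", c(0.01, 0.01, 0.01), c(2, 1, -1))))
    def <- buildIndex(cons)
    expect_setequal(def@upTaxa, c("A", "B"))
    expect_setequal(def@downTaxa, "C")
    expect_equal(def@provenance$contrast, "UC")
    # empty or one-sided consensus refuses to build an index
    consEmpty <- consensusDA(list(
        mk("bias_corrected_loglinear", rep(0.9, 3), c(1, 1, -1)),
        mk("clr_linear", rep(0.9, 3), c(1, 1, -1)),
        mk("tss_log_linear", rep(0.9, 3), c(1, 1, -1))))
    expect_error(buildIndex(consEmpty), "both directions")
})

test_that("index scores follow the log-ratio formula with pseudocount", {
    def <- methods::new("IndexDefinition", upTaxa = c("a", "b"),
                        downTaxa = c("c"), epsilon = 1e-6,
                        provenance = list())
    rel <- matrix(c(0.05, 0.05, 0.1, 0.8,
                    0.15, 0.05, 0.05, 0.75,
                    0.1, 0.1, 0, 0.8),
                  nrow = 3, byrow = TRUE,
                  dimnames = list(paste0("S", 1:3),
                                  c("a", "b", "c", "d")))
    sc <- applyIndex(def, rel)
    expect_equal(unname(sc@scores["S1"]), 0, tolerance = 1e-5)
    expect_equal(unname(sc@scores["S2"]),
                 log(0.200001 / 0.050001))
    expect_equal(unname(sc@scores["S3"]), log(0.200001 / 1e-6))
    expect_equal(sc@coverage, 1)
})

test_that("index is scale-invariant and anti-symmetric", {
    def <- methods::new("IndexDefinition", upTaxa = c("a", "b"),
                        downTaxa = c("c", "d"), epsilon = 1e-6,
                        provenance = list())
    swapped <- methods::new("IndexDefinition", upTaxa = c("c", "d"),
                            downTaxa = c("a", "b"), epsilon = 1e-6,
                            provenance = list())
    set.seed(6)
    m <- matrix(rpois(10 * 6, 40) + 1, 10)
    colnames(m) <- letters[1:6]
    rownames(m) <- paste0("S", 1:10)
    s1 <- applyIndex(def, m)@scores
    s2 <- applyIndex(def, m * 17)@scores
    expect_equal(s1, s2)
    expect_equal(applyIndex(swapped, m)@scores, -s1)
})

test_that("index taxa match across label conventions", {
    def <- methods::new("IndexDefinition",
                        upTaxa = "g__Lachnospiraceae ND3007 group",
                        downTaxa = "g__Escherichia-Shigella",
                        epsilon = 1e-6, provenance = list())
    m <- matrix(c(30L, 10L, 60L), 1, dimnames = list("S1",
        c("d__Bacteria;f__Lachnospiraceae;g__[Lachnospiraceae] ND3007",
          "d__Bacteria;g__Escherichia-Shigella", "g__Bacteroides")))
    sc <- applyIndex(def, m)
    expect_equal(sc@coverage, 1)
    expect_equal(unname(sc@scores), log(0.3 + 1e-6) - log(0.1 + 1e-6))
})

test_that("index definitions serialize and read back", {
    def <- methods::new("IndexDefinition", upTaxa = c("a", "b"),
                        downTaxa = "c", epsilon = 1e-6,
                        provenance = list(contrast = "UC",
                                          reference = "CD",
                                          alpha = 0.05))
    tf <- tempfile(fileext = ".json")
    writeIndexDefinition(def, tf)
    back <- readIndexDefinition(tf)
    expect_equal(back@upTaxa, def@upTaxa)
    expect_equal(back@downTaxa, def@downTaxa)
    expect_equal(back@epsilon, def@epsilon)
    expect_equal(back@provenance$contrast, "UC")
})

test_that("AUC equals the brute-force pairwise probability", {
    expect_equal(aucScore(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
    expect_equal(aucScore(c(0.9, 0.8, 0.7, 0.85),
                          c(TRUE, TRUE, FALSE, FALSE)), 0.75)
    expect_equal(aucScore(rep(1, 6), rep(c(TRUE, FALSE), 3)), 0.5)
    set.seed(23)
    for (i in 1:60) {
        n <- sample(4:30, 1)
        s <- sample(round(runif(n), 2))  # ties likely
        pos <- runif(n) < 0.5
        if (!any(pos) || all(pos)) next
        expect_equal(aucScore(s, pos), bruteForceAUC(s, pos))
    }
    expect_error(aucScore(1:4, rep(TRUE, 4)), "both classes")
})

test_that("AUC matches the normalized Mann-Whitney U statistic", {
    set.seed(9)
    for (i in 1:20) {
        s <- rnorm(40)
        pos <- runif(40) < 0.5
        if (!any(pos) || all(pos)) next
        U <- suppressWarnings(stats::wilcox.test(
            s[pos], s[!pos])$statistic)
        expect_equal(aucScore(s, pos),
                     unname(U) / (sum(pos) * sum(!pos)))
    }
})

test_that("location gradient is recovered and labelled", {
    locs <- c(L1_ileal = 1, L3_ileocolonic = 2, L2_colonic = 3,
              E1_proctitis = 4, E2_left_sided = 5, E3_total = 6)
    gEff <- lapply(locs, function(r) {
        s <- 0.4 * (r - 3.5)
        c(stats::setNames(rep(s, 5), plantedUp()),
          stats::setNames(rep(-s, 5), plantedDown()))
    })
    def <- methods::new("IndexDefinition", upTaxa = plantedUp(),
                        downTaxa = plantedDown(), epsilon = 1e-6,
                        provenance = list())
    coh <- makeCohort(77, n = 150, effects = gEff)
    sc <- applyIndex(def, coh$experiment)
    gr <- locationGradient(sc, sampleData(coh$experiment))
    expect_true("ordinal_trend" %in% gr$test)
    tr <- gr[gr$test == "ordinal_trend", ]
    expect_gt(tr$estimate, 0)
    expect_lt(tr$p, 0.01)
    l2 <- gr[gr$contrast == "L2_colonic vs L1_ileal", ]
    expect_gt(l2$estimate, 0)
    uc <- gr[gr$contrast == "UC vs L2_colonic", ]
    expect_gt(uc$estimate, 0)
})

test_that("gradient contrasts with absent levels are skipped with warning", {
    def <- methods::new("IndexDefinition", upTaxa = plantedUp(),
                        downTaxa = plantedDown(), epsilon = 1e-6,
                        provenance = list())
    spec <- CohortSpec(nPerGroup = c(UC = 30), nTaxa = 150)
    coh <- suppressMessages(generateCohort(spec, seed = 4))
    sc <- applyIndex(def, coh$experiment)
    expect_warning(
        expect_warning(gr <- locationGradient(
            sc, sampleData(coh$experiment)), "skipping"),
        "skipping")
})
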