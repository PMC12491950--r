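test_that("TSV count tables round-trip with ids and ordering preserved", {
    x <- MicrobiomeExperiment(tinyCounts())
    expect_equal(unname(sampleDepths(x)), c(5, 3, 7))
    tf <- tempfile(fileext = ".tsv")
    writeCountTable(x, tf)
    y <- readCountTable(tf)
    expect_identical(countMatrix(y), countMatrix(x))
    expect_identical(colnames(y), paste0("S", 1:3))
})

test_that("count table reader rejects malformed input", {
    tf <- tempfile()
    writeLines(character(0), tf)
    expect_error(readCountTable(tf), "format error")
    writeLines(c("sample_id\tgA", "S1\t3", "S1\t4"), tf)
    expect_error(readCountTable(tf), "S1")
    writeLines(c("sample_id\tgA", "S1\t-3"), tf)
    expect_error(readCountTable(tf), "non-negative")
    writeLines(c("sample_id\tgA", "S1\t2.5"), tf)
    expect_error(readCountTable(tf), "integer")
    expect_error(readCountTable(tempfile()), "not found")
})

test_that("BIOM tables are read through the adapter", {
    skip_if_not_installed("biomformat")
    m <- matrix(c(5L, 1L, 0L, 2L, 3L, 8L), nrow = 2,
                dimnames = list(c("gA", "gB"), c("S1", "S2", "S3")))
    b <- biomformat::make_biom(m)
    tf <- tempfile(fileext = ".biom")
    biomformat::write_biom(b, tf)
    x <- readCountTable(tf, format = "biom")
    expect_equal(unname(countMatrix(x, samplesAsRows = FALSE)), unname(m))
})

test_that("constructor enforces uniqueness and non-negativity", {
    m <- tinyCounts()
    rownames(m) <- c("S1", "S1", "S3")
    expect_error(MicrobiomeExperiment(m), "duplicate sample id: S1")
    m <- tinyCounts()
    m[1, 1] <- -1L
    expect_error(MicrobiomeExperiment(m), "negative")
})

test_that("metadata ingest clamps calprotectin and validates vocabularies", {
    md <- data.frame(sample_id = c("a", "b", "c"),
                     diagnosis = c("UC", "CD", "symptomatic_control"),
                     f_calprotectin = c(10, 500, 2500),
                     bss = c(3, 7, 1))
    v <- validateSampleMetadata(md)
    expect_equal(v$f_calprotectin, c(29, 500, 1801))
    md$bss[1] <- 9
    expect_error(validateSampleMetadata(md), "bss")
    md$bss[1] <- 3
    md$diagnosis[1] <- "colitis"
    expect_error(validateSampleMetadata(md), "unknown diagnosis")
})

test_that("Montreal codes must be consistent with diagnosis", {
    md <- data.frame(sample_id = c("a", "b"),
                     diagnosis = c("UC", "CD"),
                     montreal_location = c("E2_left_sided", "L1_ileal"))
    expect_silent(validateSampleMetadata(md))
    md$montreal_location <- c("L1_ileal", "E2_left_sided")
    expect_error(validateSampleMetadata(md), "inconsistent")
})

test_that("sample filtering keeps depth >= threshold inclusively", {
    m <- matrix(c(10000L, 0L, 9999L, 0L, 49000L, 1000L), nrow = 3,
                byrow = TRUE,
                dimnames = list(c("A", "B", "C"), c("g1", "g2")))
    x <- MicrobiomeExperiment(m)
    expect_message(f <- filterSamples(x, 10000), "removed 1")
    expect_identical(colnames(f), c("A", "C"))
    expect_identical(colnames(filterSamples(x, 0)), c("A", "B", "C"))
    expect_error(filterSamples(x, 1e9), "empty result")
})

test_that("rarefaction is exact-depth, bounded, and seed-deterministic", {
    m <- matrix(c(5L, 3L, 2L), nrow = 1,
                dimnames = list("S1", c("a", "b", "c")))
    x <- MicrobiomeExperiment(m)
    expect_equal(unname(countMatrix(rarefy(x, depth = 10, seed = 1))),
                 unname(m))
    r5 <- countMatrix(rarefy(x, depth = 5, seed = 1))
    expect_equal(sum(r5), 5)
    expect_true(all(r5 <= m))
    expect_identical(countMatrix(rarefy(x, depth = 5, seed = 42)),
                     countMatrix(rarefy(x, depth = 5, seed = 42)))
    expect_error(rarefy(x, depth = 100, seed = 1), "empty result")
    expect_error(rarefy(x, depth = 5), "seed")
})

test_that("rarefaction preserves expected proportions", {
    m <- matrix(c(10000L, 6000L, 4000L), nrow = 1,
                dimnames = list("S1", c("a", "b", "c")))
    x <- MicrobiomeExperiment(m)
    props <- vapply(seq_len(300), function(s)
        countMatrix(rarefy(x, depth = 9503, seed = s))[1, ] / 9503,
        numeric(3))
    expect_true(all(abs(rowMeans(props) - c(0.5, 0.3, 0.2)) < 0.01))
})

test_that("relative abundance and CLR transforms satisfy their identities", {
    expect_equal(unname(toRelative(matrix(c(2, 2, 4), 1))[1, ]),
                 c(0.25, 0.25, 0.5))
    expect_equal(unname(toRelative(matrix(c(0, 0, 9), 1))[1, ]),
                 c(0, 0, 1))
    expect_error(toRelative(matrix(0, 1, 3,
                                   dimnames = list("S1", letters[1:3]))),
                 "S1")
    expect_equal(unname(clrTransform(matrix(c(1, 1, 1), 1))[1, ]),
                 c(0, 0, 0))
    expect_equal(unname(clrTransform(matrix(c(3, 0), 1), 0.5)[1, ]),
                 c(log(7) / 2, -log(7) / 2))
    set.seed(9)
    m <- matrix(rpois(200, 5), 10)
    expect_true(all(abs(rowSums(clrTransform(m))) < 1e-9))
    expect_true(all(abs(rowSums(toRelative(m + 1)) - 1) < 1e-9))
    expect_error(clrTransform(m, pseudocount = 0), "positive")
})

test_that("filter then rarefy is idempotent at equal depth", {
    coh <- makeCohort(3, n = 15, nTaxa = 40)
    r1 <- rarefy(filterSamples(coh$experiment, 9000), 8000, seed = 5)
    r2 <- suppressMessages(rarefy(filterSamples(r1, 8000), 8000, seed = 6))
    expect_identical(countMatrix(r1), countMatrix(r2))
})

test_that("taxonomy labels normalize to canonical genus keys", {
    expect_equal(
        normalizeTaxonNames(c(
            "d__Bacteria;f__Lachnospiraceae;g__Lachnospiraceae ND3007 group",
            "[Lachnospiraceae] ND3007",
            "g__Escherichia-Shigella",
            "Bacteroides")),
        c("lachnospiraceae_nd3007", "lachnospiraceae_nd3007",
          "escherichia_shigella", "bacteroides"))
})
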