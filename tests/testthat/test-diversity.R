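test_that("shannon matches hand-computed values and the uniform maximum", {
    expect_equal(unname(shannon(c(10, 10, 10, 10))), log(4))
    expect_equal(unname(shannon(c(7, 0, 0))), 0)
    expect_equal(unname(shannon(c(3, 1))),
                 -(0.75 * log(0.75) + 0.25 * log(0.25)))
    expect_error(shannon(c(0, 0)), "zero-total")
    set.seed(4)
    for (i in 1:20) {
        k <- sample(2:12, 1)
        v <- rpois(k, 30) + 1
        expect_lte(unname(shannon(v)), log(k) + 1e-12)
    }
})

test_that("observed richness counts taxa with at least one read", {
    expect_equal(unname(observedTaxa(c(3, 0, 1, 0))), 2)
    coh <- makeCohort(2, n = 10, nTaxa = 50)
    a <- alphaDiversity(coh$experiment)
    expect_true(all(a$observed_taxa <= 50))
    expect_true(all(a$shannon >= 0))
})

test_that("Bray-Curtis satisfies its formula and metric-like properties", {
    m <- matrix(c(2, 0, 0, 2), 2, byrow = TRUE)
    expect_equal(as.numeric(suppressWarnings(brayCurtis(m))), 1)
    m2 <- matrix(c(6, 2, 2, 6), 2, byrow = TRUE)
    expect_equal(as.numeric(brayCurtis(m2)), 0.5)
    set.seed(8)
    r <- matrix(rpois(12 * 30, 15), 12)
    D <- as.matrix(suppressWarnings(brayCurtis(r)))
    expect_equal(D, t(D))
    expect_true(all(diag(D) == 0))
    expect_true(all(D >= 0 & D <= 1))
    expect_warning(brayCurtis(matrix(c(1, 2, 5, 9), 2)), "unequal")
    expect_error(brayCurtis(matrix(c(1, 2, 5, 9), 2),
                            requireEqualDepth = TRUE), "unequal")
})

test_that("permanova with exact enumeration matches the brute-force oracle", {
    for (s in 1:4) {
        set.seed(s)
        m <- matrix(rpois(6 * 10, 12), 6)
        g <- rep(c("a", "b"), each = 3)
        d <- suppressWarnings(brayCurtis(m))
        res <- permanova(d, g, nPermutations = "exact")
        orc <- permanovaOracleExhaustive(d, g)
        expect_equal(res@statistic, orc$F, tolerance = 1e-10)
        expect_equal(res@p, orc$p, tolerance = 1e-10)
    }
})

test_that("permanova returns an R-squared partition and a valid p", {
    set.seed(21)
    m <- matrix(rpois(30 * 25, 12), 30)
    g <- rep(c("a", "b", "c"), each = 10)
    res <- permanova(suppressWarnings(brayCurtis(m)), g,
                     nPermutations = 199, seed = 4)
    expect_gte(res@rSquared, 0)
    expect_lte(res@rSquared, 1)
    expect_gte(res@p, 1 / 200)
    expect_lte(res@p, 1)
    expect_error(permanova(dist(m[1:3, ]), c("a", "a", "b")),
                 "at least 2")
})

test_that("permdisp detects a dispersion difference and not a pure shift", {
    set.seed(31)
    tight <- matrix(rnorm(25 * 4, sd = 0.2), 25)
    wide <- matrix(rnorm(25 * 4, sd = 1.0), 25)
    d <- dist(rbind(tight, wide))
    g <- rep(c("t", "w"), each = 25)
    res <- permdisp(d, g, nPermutations = 199, seed = 2)
    expect_lt(res@p, 0.05)
    dd <- dispersionDistances(d, g)
    expect_lt(mean(dd[g == "t"]), mean(dd[g == "w"]))
    idGroup <- matrix(rep(c(1, 2, 3, 4), 10), 10, byrow = TRUE)
    d2 <- dist(rbind(idGroup, matrix(rnorm(10 * 4), 10)))
    g2 <- rep(c("id", "noise"), each = 10)
    expect_true(all(dispersionDistances(d2, g2)[g2 == "id"] < 1e-8))
})

test_that("alpha comparison recovers a planted group deficit", {
    set.seed(12)
    n <- 200
    md <- data.frame(diagnosis = rep(c("UC", "CD"), each = n),
                     age = rnorm(2 * n, 40, 12),
                     sex = sample(c("female", "male"), 2 * n, TRUE),
                     bmi = rnorm(2 * n, 25, 4),
                     antibiotics = runif(2 * n) < 0.1)
    alpha <- 2.5 - 0.5 * (md$diagnosis == "CD") +
        0.01 * (md$age - 40) + rnorm(2 * n, 0, 0.3)
    res <- compareAlpha(alpha, md, reference = "UC")
    expect_equal(res$estimate[res$contrast == "CD vs UC"], -0.5,
                 tolerance = 0.2)
    expect_lt(res$p[1], 0.001)
})

test_that("alpha comparison is calibrated and confounder-adjusted", {
    pvals <- vapply(1:200, function(s) {
        set.seed(s)
        md <- data.frame(diagnosis = rep(c("UC", "CD"), each = 40),
                         age = rnorm(80, 40, 10),
                         sex = sample(c("f", "m"), 80, TRUE),
                         bmi = rnorm(80, 25, 4),
                         antibiotics = runif(80) < 0.1)
        alpha <- 2.5 + rnorm(80, 0, 0.4)
        compareAlpha(alpha, md)$p[1]
    }, 1)
    expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
    # age-confounded design: age drives alpha and differs by group
    confounded <- vapply(1:40, function(s) {
        set.seed(1000 + s)
        age <- c(rnorm(60, 30, 5), rnorm(60, 50, 5))
        md <- data.frame(diagnosis = rep(c("UC", "CD"), each = 60),
                         age = age,
                         sex = sample(c("f", "m"), 120, TRUE),
                         bmi = rnorm(120, 25, 4),
                         antibiotics = runif(120) < 0.1)
        alpha <- 2 + 0.03 * age + rnorm(120, 0, 0.3)
        compareAlpha(alpha, md)$p[1]
    }, 1)
    expect_gte(mean(confounded > 0.05), 0.9)
})

test_that("constant covariates are dropped with a warning", {
    md <- data.frame(diagnosis = rep(c("UC", "CD"), each = 20),
                     age = rnorm(40, 40),
                     sex = sample(c("f", "m"), 40, TRUE),
                     bmi = rnorm(40, 25), antibiotics = FALSE)
    expect_warning(res <- compareAlpha(rnorm(40, 2.5), md),
                   "constant covariate")
    expect_s3_class(res, "data.frame")
})

test_that("principal coordinates and the rank test utility behave", {
    set.seed(5)
    m <- rbind(matrix(rnorm(20 * 5), 20),
               matrix(rnorm(20 * 5, mean = 2), 20))
    pc <- principalCoordinates(dist(m))
    expect_equal(dim(pc$scores), c(40, 2))
    g <- rep(c("a", "b"), each = 20)
    rt <- rankTest(pc$scores[, 1], g)
    expect_lt(rt$p, 0.01)
    expect_error(rankTest(rnorm(9), gl(3, 3)), "two groups")
})
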