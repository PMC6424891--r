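test_that("fold ratios follow the condition-2-over-condition-1 convention", {
    expect_equal(foldRatio(0.001, 0.02), 20)
    expect_equal(foldRatio(0.37, 0.37), 1)
    # zero baseline: undefined, never infinity
    expect_true(is.na(foldRatio(0, 0.01)))
    expect_error(foldRatio(-0.1, 0.5), "non-negative")
})

test_that("the pooled z-test reproduces hand-evaluated values", {
    # frozen from independent evaluation of the pooled-z formula and
    # cross-checked against stats::prop.test(correct = FALSE)
    r <- zTestEqualTranscription(100, 1e5, 50, 1e5)
    expect_equal(r$statistic, 4.084015, tolerance = 1e-6)
    expect_equal(r$p_value, 4.426423e-05, tolerance = 1e-6)

    pt <- prop.test(c(100, 50), c(1e5, 1e5), correct = FALSE)
    expect_equal(r$p_value, pt$p.value, tolerance = 1e-12)
    expect_equal(r$statistic^2, unname(pt$statistic), tolerance = 1e-12)

    # symmetry and antisymmetry
    same <- zTestEqualTranscription(70, 1e4, 70, 1e4)
    expect_equal(same$statistic, 0)
    expect_equal(same$p_value, 1)
    sw <- zTestEqualTranscription(50, 1e5, 100, 1e5)
    expect_equal(sw$statistic, -r$statistic)
    expect_equal(sw$p_value, r$p_value)

    expect_error(zTestEqualTranscription(1, 0, 2, 10), "positive")
})

test_that("the 2x2 chi-square test matches stats::chisq.test", {
    r <- chiSquareEqualTranscription(30, 1e4, 10, 1e4)
    expect_equal(r$statistic, 10.02004, tolerance = 1e-6)
    expect_equal(r$p_value, 1.548461e-03, tolerance = 1e-6)

    set.seed(123)
    for (i in 1:25) {
        N1 <- sample(50:5000, 1); N2 <- sample(50:5000, 1)
        c1 <- rbinom(1, N1, runif(1, 0.01, 0.4))
        c2 <- rbinom(1, N2, runif(1, 0.01, 0.4))
        mine <- suppressWarnings(
            chiSquareEqualTranscription(c1, N1, c2, N2))
        ref <- suppressWarnings(chisq.test(
            matrix(c(c1, N1 - c1, c2, N2 - c2), 2, byrow = TRUE),
            correct = FALSE))
        expect_equal(mine$statistic, unname(ref$statistic),
                     tolerance = 1e-9)
        expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
    }

    ident <- chiSquareEqualTranscription(40, 1000, 40, 1000)
    expect_equal(ident$statistic, 0)
    expect_equal(ident$p_value, 1)
    expect_warning(chiSquareEqualTranscription(0, 100, 0, 200),
                   "degenerate")
})

test_that("chi-square equals z-squared on random 2x2 tables", {
    set.seed(2024)
    n <- 500
    N1 <- sample(20:20000, n, replace = TRUE)
    N2 <- sample(20:20000, n, replace = TRUE)
    c1 <- rbinom(n, N1, runif(n, 0.001, 0.5))
    c2 <- rbinom(n, N2, runif(n, 0.001, 0.5))
    z <- zTestEqualTranscription(c1, N1, c2, N2)
    x2 <- suppressWarnings(chiSquareEqualTranscription(c1, N1, c2, N2))
    nz <- x2$statistic > 0
    expect_true(any(nz))
    expect_lt(max(abs(z$statistic[nz]^2 - x2$statistic[nz]) /
                  x2$statistic[nz]), 1e-9)
    expect_equal(z$p_value, x2$p_value, tolerance = 1e-9)
})

test_that("ratios are classified against inclusive fold thresholds", {
    sc <- thresholdScheme()
    expect_identical(
        classifyChange(c(12, 2.5, 1.5, 0.7, 0.3, 0.08, NA), sc),
        c("up_10x", "up_2x", "unchanged", "unchanged", "down_50pct",
          "down_90pct", "undefined"))
    # boundaries belong to the stronger class by default
    expect_identical(classifyChange(c(2, 10, 0.5, 0.1), sc),
                     c("up_2x", "up_10x", "down_50pct", "down_90pct"))
    excl <- thresholdScheme(boundaryInclusive = FALSE)
    expect_identical(classifyChange(c(2, 0.5), excl),
                     c("unchanged", "unchanged"))

    # monotone step function partitioning [0, Inf)
    ratios <- sort(c(0, 10^seq(-3, 3, length.out = 200)))
    cls <- classifyChange(ratios, sc)
    ord <- c(down_90pct = 1, down_50pct = 2, unchanged = 3,
             up_2x = 4, up_10x = 5)
    expect_true(all(diff(ord[cls]) >= 0))
    expect_true(all(cls %in% changeClasses(sc)))

    # single-level scheme uses its own labels
    one <- thresholdScheme(up = 2, down = 0.5)
    expect_identical(classifyChange(c(3, 0.4), one),
                     c("up_2x", "down_50pct"))
    expect_error(classifyChange(-1, sc), "non-negative")
})

test_that("compareConditions dispatches on baseline replication", {
    u <- c(gA = 0L, gB = 0L, gC = 0L)
    mk <- function(id, v) OrfCountTable(id, u + v, sum(v))
    base3 <- SampleGroup("ctrl", list(mk("c1", c(50L, 30L, 20L)),
                                      mk("c2", c(55L, 28L, 17L)),
                                      mk("c3", c(48L, 33L, 19L))))
    single <- SampleGroup("trt", mk("t1", c(20L, 60L, 20L)))

    res <- compareConditions(base3, single)
    expect_identical(unique(res$test_used), "z_test")
    expect_identical(res$feature_id, c("gA", "gB", "gC"))
    # pooled baseline counts
    expect_identical(res$c_baseline, c(153L, 91L, 56L))
    expect_equal(res$N_baseline, rep(300, 3))

    res2 <- compareConditions(SampleGroup("a", mk("a1", c(30L, 30L, 40L))),
                              single)
    expect_identical(unique(res2$test_used), "chi_square")

    # q-values are BH over all ORFs and never below p
    expect_equal(res$q_value, p.adjust(res$p_value, "BH"))
    expect_true(all(res$q_value >= res$p_value))
})

test_that("self-comparison yields unit ratios and p = 1", {
    v <- c(g1 = 120L, g2 = 40L, g3 = 7L)
    s <- OrfCountTable("x", v, sum(v))
    res <- compareConditions(SampleGroup("c", s), SampleGroup("c2", s))
    expect_true(all(res$ratio == 1))
    expect_true(all(res$p_value == 1))
    expect_true(all(res$change_class == "unchanged"))
})

test_that("zero baselines stay testable; Haldane shift gives finite ratios", {
    b <- SampleGroup("c", OrfCountTable("b", c(g1 = 0L, g2 = 100L), 100L))
    o <- SampleGroup("t", OrfCountTable("o", c(g1 = 30L, g2 = 70L), 100L))
    res <- compareConditions(b, o)
    expect_true(is.na(res$ratio[1]))
    expect_identical(res$change_class[1], "undefined")
    expect_lt(res$p_value[1], 0.001)   # counts still permit testing

    hal <- compareConditions(b, o, pseudocount = "haldane")
    expect_true(all(is.finite(hal$ratio)))
    expect_gt(hal$ratio[1], 1)
})

test_that("mismatched feature universes are rejected with the offender", {
    a <- SampleGroup("c", OrfCountTable("a", c(g1 = 5L, g2 = 5L), 10L))
    b <- SampleGroup("t", OrfCountTable("b", c(g1 = 5L, gX = 5L), 10L))
    expect_error(compareConditions(a, b), "gX")
})
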