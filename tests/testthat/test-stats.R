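test_that("skews follow the closed form, flag undefined denominators, and antisymmetrize", {
    s1 <- skews("GGGG")
    expect_equal(s1$gc_skew, 1)
    expect_true(is.na(s1$at_skew))
    expect_false(s1$at_defined)
    s2 <- skews("GACT")
    expect_equal(s2$gc_skew, 0)
    expect_equal(s2$at_skew, 0)
    set.seed(8)
    for (i in 1:20) {
        s <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
        a <- skews(s); b <- skews(bottomStrand(s))
        expect_equal(b$gc_skew, -a$gc_skew)
        expect_equal(b$at_skew, -a$at_skew)
        expect_true(abs(a$gc_skew) <= 1 && abs(a$at_skew) <= 1)
    }
})

test_that("pairwise identity is symmetric, 100 iff equal, 0 for disjoint alphabets", {
    expect_equal(pairwiseIdentity("ACGTACGT", "ACGTACGT"), 100)
    expect_equal(pairwiseIdentity("AAAA", "TTTT"), 0)
    a <- "GTTAGGCATTCAAAGGTTAACC"
    b <- "GTTAGGCTTTCAAAGCTTAACC"
    expect_equal(pairwiseIdentity(a, b), pairwiseIdentity(b, a))
    expect_lt(pairwiseIdentity(a, b), 100)
    expect_error(pairwiseIdentity("", "ACGT"), "non-empty")
})

test_that("direct repeats are maximal, coordinate-correct and length-sorted", {
    expect_equal(nrow(directRepeats("AAAAAA", "CCCCCC", minLen = 4)), 0L)
    s <- "GATTACAGATTACA"
    dr <- directRepeats(s, s, minLen = 4)
    expect_equal(dr$length[1], nchar(s))
    expect_equal(dr$start_a[1], 1L)
    # a single planted shared word
    a <- paste0("AAAAAAAA", "GTTAGGC", "AAAAAAAA")
    b <- paste0("CCCCCCCC", "GTTAGGC", "CCCCCCCC")
    hit <- directRepeats(a, b, minLen = 5)
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$seq, "GTTAGGC")
    expect_equal(hit$start_a, 9L)
    expect_equal(hit$start_b, 9L)
    expect_error(directRepeats("ACGT", "ACGT", minLen = 3), ">= 4")
})

test_that("rank-sum test is exact for small tie-free samples and approximates well", {
    r <- rankSumTest(c(1, 2, 3), c(10, 11, 12))
    expect_equal(r$method, "exact")
    expect_equal(r$p_two_sided, 0.1)       # 2 / choose(6, 3)
    expect_equal(rankSumTest(c(1, 2, 3), c(1, 2, 3))$p_two_sided, 1,
                 tolerance = 0.01)
    expect_equal(rankSumTest(rep(5, 4), rep(5, 6))$p_two_sided, 1)

    # the corrected normal approximation tracks exact enumeration at
    # n = 8 vs 8: within ~0.011 anywhere (worst case near p ~ 0.5) and
    # much closer in the separated-samples regime the pipeline tests in
    set.seed(99)
    for (i in 1:10) {
        x <- rnorm(8); y <- rnorm(8, 0.8)
        r16 <- rankSumTest(x, y)      # 8 + 8 is past the exact regime
        expect_equal(r16$method, "normal_approximation")
        expect_lt(abs(r16$p_two_sided - exactRankSumP(x, y)), 0.012)
    }
})

test_that("linear fit reproduces closed-form OLS", {
    f <- linearFit(1:5, 2 * (1:5) + 1)
    expect_equal(f$slope, 2)
    expect_equal(f$intercept, 1)
    expect_equal(f$r_squared, 1)
    f0 <- linearFit(1:5, rep(3, 5))
    expect_equal(f0$slope, 0)
    expect_equal(f0$r_squared, 0)
    expect_error(linearFit(rep(2, 5), 1:5), "variance")

    x <- c(1, 2, 4, 7, 9); y <- c(2.2, 2.8, 4.1, 7.4, 8.9)
    # closed form by hand
    bx <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    ax <- mean(y) - bx * mean(x)
    r2 <- 1 - sum((y - ax - bx * x)^2) / sum((y - mean(y))^2)
    f2 <- linearFit(x, y)
    expect_equal(f2$slope, bx)
    expect_equal(f2$intercept, ax)
    expect_equal(f2$r_squared, r2)
})

test_that("cohort summary computes threshold proportions per group", {
    tab <- data.frame(pfold = c(0.2, 0.5, 0.05, 0.01),
                      length = c(60, 70, 80, 90))
    s <- cohortSummary(tab, rep("MI", 4))
    expect_equal(s$prop_pfold_above, 0.5)
    expect_equal(s$median_length, 75)
    one <- cohortSummary(data.frame(pfold = 0.3, length = 64), "X")
    expect_equal(one$median_length, 64)
    # threshold is strict: pfold exactly at the threshold does not count
    s2 <- cohortSummary(data.frame(pfold = c(0.1, 0.11), length = c(1, 2)),
                        rep("g", 2))
    expect_equal(s2$prop_pfold_above, 0.5)
    # low band is a closed interval
    s3 <- cohortSummary(data.frame(pfold = c(1e-5, 1e-7, 1e-4, 1e-8),
                                   length = 1:4), rep("g", 4))
    expect_equal(s3$prop_pfold_low_band, 0.5)
})
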