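test_that("GC-disparity profile matches hand counts and flips under complementation", {
    expect_equal(gcDisparityProfile("GGCC"), c(1, 2, 1, 0))
    set.seed(3)
    s <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE,
                      prob = c(.2, .22, .33, .25)), collapse = "")
    prof <- gcDisparityProfile(s)
    chars <- strsplit(s, "")[[1]]
    expect_equal(prof[length(prof)], sum(chars == "G") - sum(chars == "C"))
    expect_equal(gcDisparityProfile(bottomStrand(s))[10000], -prof[10000])
    # ambiguity codes contribute nothing
    expect_equal(gcDisparityProfile("GNCN"), c(1, 1, 0, 0))
})

test_that("replichore inference recovers a planted oriC and passes explicit oriC through", {
    sr <- generateReplicon(repliconLength = 30000L, oric = 1L, seed = 11)
    prof <- gcDisparityProfile(sr$sequence)
    map <- inferReplichores(prof)
    L <- length(prof)
    circDist <- function(a, b, L) min(abs(a - b), L - abs(a - b))
    expect_lte(circDist(oriC(map), 1L, L), 0.02 * L)
    expect_lte(circDist(terminus(map), terminus(sr$map), L), 0.02 * L)

    m2 <- inferReplichores(prof, oric = 123L)
    expect_identical(oriC(m2), 123L)
    expect_error(inferReplichores(prof, circular = FALSE), "circular")
})

test_that("flat or signal-free profiles are indeterminate without an oriC", {
    expect_error(inferReplichores(gcDisparityProfile(strrep("A", 5000))),
                 "indeterminate")
    sr0 <- generateReplicon(repliconLength = 20000L, skewStrength = 0,
                            seed = 4)
    expect_error(inferReplichores(gcDisparityProfile(sr0$sequence)),
                 "indeterminate")
})

test_that("template class flips with strand and replichore and double-flips to identity", {
    map <- replichoreMap(1000L, oric = 1L)   # ter at 501
    p1 <- 100L                                # increasing arc
    p2 <- 700L                                # decreasing arc
    expect_false(templateClass(p1, "+", map) == templateClass(p1, "-", map))
    expect_false(templateClass(p1, "+", map) == templateClass(p2, "+", map))
    expect_equal(templateClass(p1, "+", map), templateClass(p2, "-", map))
    # convention: minus strand is the leading template where forks move right
    expect_equal(templateClass(p1, "-", map), "leading_template")
    expect_equal(forkDirection(map, c(1L, 500L, 501L, 1000L)),
                 c("increasing", "increasing", "decreasing", "decreasing"))
})

test_that("array aggregation splits on the distance threshold", {
    gr <- GenomicRanges::GRanges("r", IRanges::IRanges(
        c(1, 1101, 2201, 22301), width = 100))
    # gaps: 1 kb, 1 kb, 20 kb
    expect_equal(aggregateArray(gr, 4000), c(1, 1, 1, 2))
    expect_equal(aggregateArray(gr, 15000), c(1, 1, 1, 2))
    expect_equal(aggregateArray(gr, 25000), c(1, 1, 1, 1))
})

test_that("orientation labels are unanimous, majority-with-flag, or mixed", {
    map <- replichoreMap(10000L, oric = 1L)
    gr <- GenomicRanges::GRanges("chr", IRanges::IRanges(
        c(100, 700, 1300), width = 60), strand = "-")
    rec <- IntegronRecord("chr", gr)
    o <- orientIntegron(rec, map)
    expect_equal(o$orientation, "lagging_template")
    expect_false(o$mixed)

    # 3 vs 1 split: majority label, mixed flag raised
    gr2 <- GenomicRanges::GRanges("chr", IRanges::IRanges(
        c(100, 700, 1300, 1900), width = 60),
        strand = c("-", "-", "-", "+"))
    o2 <- orientIntegron(IntegronRecord("chr", gr2), map)
    expect_equal(o2$orientation, "lagging_template")
    expect_true(o2$mixed)

    # an array spanning ter flips class mid-array; 2 vs 2 is a tie -> mixed
    gr3 <- GenomicRanges::GRanges("chr", IRanges::IRanges(
        c(4800, 4900, 5100, 5200), width = 50), strand = "-")
    o3 <- orientIntegron(IntegronRecord("chr", gr3), map)
    expect_true(o3$mixed)
    expect_equal(o3$orientation, "mixed")
    expect_equal(length(unique(o3$perSite)), 2L)
})

test_that("cassette metrics use start-to-start lengths and partition CDSs", {
    gr <- GenomicRanges::GRanges("chr", IRanges::IRanges(
        c(100, 700), width = 60), strand = "-")
    rec <- IntegronRecord("chr", gr)
    cm <- cassetteMetrics(rec)
    expect_equal(cm$cassettes$length, 600)

    single <- IntegronRecord("chr", gr[1])
    expect_equal(nrow(cassetteMetrics(single)$cassettes), 0L)

    overl <- GenomicRanges::GRanges("chr", IRanges::IRanges(
        c(100, 140), width = 60), strand = "-")
    expect_error(cassetteMetrics(IntegronRecord("chr", overl)),
                 "overlapping")

    cds <- GenomicRanges::GRanges("chr", IRanges::IRanges(
        c(200, 5000, 9000), width = c(400, 900, 800)))
    S4Vectors::mcols(cds)$is_ARG <- c(FALSE, FALSE, TRUE)
    cm2 <- cassetteMetrics(rec, cds)
    expect_equal(cm2$summary$mean_cds_inside, 400)
    expect_equal(cm2$summary$mean_cds_outside, 850)
    expect_equal(cm2$summary$replicon_minus_integron, 450)
    cm3 <- cassetteMetrics(rec, cds, excludeARG = TRUE)
    expect_equal(cm3$summary$mean_cds_outside, 900)
})

test_that("cassette lengths on a tiled circular array sum to the array span", {
    L <- 5000L
    starts <- c(100L, 900L, 1900L, 3100L)
    gr <- GenomicRanges::GRanges("c", IRanges::IRanges(starts, width = 60),
                                 strand = "-")
    cm <- cassetteMetrics(IntegronRecord("c", gr), repliconLength = L)
    expect_equal(sum(cm$cassettes$length),
                 starts[length(starts)] - starts[1])
})

test_that("SCI/MI classification follows the rule precedence", {
    mk <- function(n) IntegronRecord("chr", GenomicRanges::GRanges(
        "chr", IRanges::IRanges(seq(1, by = 700, length.out = n),
                                width = 60), strand = "-"))
    expect_equal(as.character(classifyIntegron(mk(20))), "SCI")
    expect_equal(as.character(classifyIntegron(mk(19))), "unknown")
    expect_equal(as.character(classifyIntegron(mk(3), onPlasmid = TRUE)),
                 "MI")
    expect_equal(as.character(
        classifyIntegron(mk(5), fractionOfStrainsPresent = 1)), "SCI")
    expect_equal(as.character(
        classifyIntegron(mk(5), fractionOfStrainsPresent = 0.5)), "MI")
    expect_equal(as.character(
        classifyIntegron(mk(2), integraseClass = "class1")), "MI")
    # both SCI and MI criteria true: SCI retained, conflict flagged
    res <- classifyIntegron(mk(25), onPlasmid = TRUE)
    expect_equal(as.character(res), "SCI")
    expect_true(attr(res, "conflict"))
})
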