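test_that("exhaustive enumeration matches hand counts and an independent counter", {
    # no complementary pair possible: only the open chain
    expect_equal(nrow(enumerateStructures("AAAA")), 1L)
    expect_equal(enumerateStructures("AAAA")$structure, "....")
    # GAAAC with min loop 3: open chain and the single (1, 5) pair
    en <- enumerateStructures("GAAAC")
    expect_setequal(en$structure, c(".....", "(...)"))
    # counts agree with an independently written recursive counter
    for (s in c("GGAAACC", "GGGAAACCC", "GCGCAAAGCGC", "ACGTACGTACGT")) {
        expect_equal(nrow(enumerateStructures(s)),
                     countStructuresOracle(s), info = s)
    }
    expect_error(enumerateStructures(strrep("AC", 11)), "> 20 nt")
})

test_that("fold handles the open chain and reproduces the enumeration MFE", {
    f0 <- foldSequence("AAAAAA")
    expect_equal(mfeEnergy(f0), 0)
    expect_equal(mfeStructure(f0), "......")
    expect_lte(ensembleEnergy(f0), 0)

    f <- foldSequence("GGGGAAAACCCC")
    or <- enumThermo("GGGGAAAACCCC")
    expect_equal(mfeStructure(f), "((((....))))")
    expect_equal(mfeEnergy(f), or$mfe, tolerance = 1e-12)
    expect_equal(ensembleEnergy(f), or$Eens, tolerance = 1e-9)
})

test_that("DP equals the enumeration oracle on random short sequences, with and without constraints", {
    set.seed(20240601)
    model <- referenceEnergyModel()
    for (i in 1:60) {
        n <- sample(5:18, 1)
        s <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
        or <- enumThermo(s, model)
        f <- foldSequence(s, model)
        expect_equal(mfeEnergy(f), or$mfe, tolerance = 1e-9)
        expect_equal(ensembleEnergy(f), or$Eens, tolerance = 1e-9)
        # the reported MFE structure really has the reported energy
        expect_equal(structureEnergy(s, mfeStructure(f), model),
                     mfeEnergy(f), tolerance = 1e-12)

        # constrain a random admissible pair and compare again
        en <- enumerateStructures(s, model)
        paired <- en$structure[en$structure != strrep(".", n)]
        if (!length(paired)) next
        pr <- parseDotBracket(sample(paired, 1))
        cs <- constraintSet(pr[sample(nrow(pr), 1), , drop = FALSE])
        orc <- enumThermo(s, model, cs)
        fc <- foldSequence(s, model, cs)
        expect_equal(mfeEnergy(fc), orc$mfe, tolerance = 1e-9)
        expect_equal(ensembleEnergy(fc), orc$Eens, tolerance = 1e-9)
    }
})

test_that("unsatisfiable constraints raise the empty-ensemble signal and pfold maps it to 0", {
    cs <- constraintSet(cbind(2L, 8L))   # A cannot pair A
    expect_error(foldSequence("AAAAAAAAAA", constraints = cs),
                 class = "attCfold_empty_ensemble")
    p <- pfold("AAAAAAAAAA", constraints = cs)
    expect_equal(pfoldValue(p), 0)
})

test_that("pfold is 1 under an empty constraint set and matches the enumeration ratio", {
    set.seed(7)
    for (i in 1:5) {
        s <- paste(sample(c("A", "C", "G", "T"), 14, TRUE), collapse = "")
        expect_equal(pfoldValue(pfold(s, constraints = constraintSet())), 1)
    }
    # 15-nt toy: pfold equals the constrained share of the Boltzmann sum
    s <- "GGGCAAAAGCCCAAA"
    model <- referenceEnergyModel()
    en <- enumerateStructures(s, model)
    rt <- 1.98717e-3 * model@temperature
    cs <- constraintSet(cbind(1L, 12L))
    keep <- vapply(en$structure, function(x) {
        p <- parseDotBracket(x)
        any(p[, 1] == 1 & p[, 2] == 12)
    }, TRUE)
    expected <- sum(exp(-en$energy[keep] / rt)) / sum(exp(-en$energy / rt))
    expect_equal(pfoldValue(pfold(s, model, cs)), expected, tolerance = 1e-9)
})

test_that("pfold never increases as constraints grow", {
    set.seed(42)
    g <- toySite(seed = 13)
    site <- g$site
    cs <- recombinogenicConstraints(site)
    p <- forcedPairs(cs)
    model <- referenceEnergyModel()
    bs <- bottomStrand(site)
    prev <- 1
    for (k in c(1, 4, 8, nrow(p))) {
        pk <- pfoldValue(pfold(bs, model,
                               constraintSet(p[seq_len(k), , drop = FALSE])))
        expect_lte(pk, prev + 1e-12)
        prev <- pk
    }
})

test_that("strand stability gap has the documented sign convention and is deterministic", {
    # self-reverse-complement sequence: both strands identical, gap 0
    pal <- "GGGGAAAATTTTCCCC"
    expect_equal(bottomStrand(pal), pal)
    site <- suppressWarnings(AttCSite("pal", pal))
    expect_equal(strandStabilityGap(site), 0)

    # top strand is A/C only (no pairs); its bottom strand is G/T rich and
    # can fold through wobble pairs: only the bottom strand pairs
    site2 <- suppressWarnings(AttCSite("asym", "CCCCAAAACCCCAAAA"))
    gap <- strandStabilityGap(site2)
    or_bs <- enumThermo(bottomStrand("CCCCAAAACCCCAAAA"))
    or_ts <- enumThermo("CCCCAAAACCCCAAAA")
    expect_equal(gap, or_bs$mfe - or_ts$mfe, tolerance = 1e-12)
    expect_lt(gap, 0)

    g <- toySite(seed = 17)
    expect_identical(strandStabilityGap(g$site), strandStabilityGap(g$site))
    gc <- strandStabilityGap(g$site, mode = "constrained")
    expect_true(is.finite(gc))
})

test_that("constrained and unconstrained MFE agree when the MFE already satisfies the constraints", {
    # palindromic stem: the unconstrained MFE contains the forced pairs
    s <- "GGGGCAAAAGCCCC"
    f <- foldSequence(s)
    pr <- parseDotBracket(mfeStructure(f))
    cs <- constraintSet(pr[1:2, , drop = FALSE])
    fc <- foldSequence(s, constraints = cs)
    expect_equal(mfeEnergy(fc), mfeEnergy(f), tolerance = 1e-12)
})

test_that("the RNAfold DNA backend satisfies the pfold contract", {
    skip_if(!viennaAvailable(), "RNAfold executable or DNA parameters absent")
    s <- "GGGGGAAAAACCCCC"
    un <- viennaFold(s)
    expect_true(is.finite(un$mfe) && is.finite(un$ensemble))
    expect_lte(un$ensemble, un$mfe + 0.01)
    cs <- constraintSet(cbind(1:3, 15:13))
    vp <- viennaPfold(s, cs)
    expect_gte(vp$Ec, vp$Eu - 0.02)
    expect_gte(vp$pfold, 0)
    expect_lte(vp$pfold, 1)
    # site-level call folds the bottom strand under its own constraints
    g <- toySite(seed = 23)
    vs <- viennaPfold(g$site)
    expect_gt(vs$pfold, 0)
})
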