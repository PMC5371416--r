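test_that("bottomStrand is the reverse complement, an involution, and matches a naive oracle", {
    expect_equal(bottomStrand("GTTA"), "TAAC")
    set.seed(101)
    for (i in 1:10) {
        s <- paste(sample(c("A", "C", "G", "T", "R", "Y", "N"), 60, TRUE,
                          prob = c(.23, .23, .23, .23, .03, .03, .02)),
                   collapse = "")
        expect_equal(bottomStrand(s), naiveRevComp(s))
        expect_equal(bottomStrand(bottomStrand(s)), s)
    }
    expect_error(bottomStrand("ACGX"), "invalid-alphabet")
})

test_that("AttCSite validates alphabet, boxes and soft length bounds", {
    expect_warning(AttCSite("short", "ACGTACGT"), "57-141")
    expect_silent(s <- AttCSite("ok", strrep("ACGT", 20)))
    expect_equal(length(topStrand(s)), 80L)
    # boxes outside the sequence are rejected
    b <- boxAnnotation(rDPrime = IRanges::IRanges(94, 100),
                       lDPrime = IRanges::IRanges(60, 67),
                       lPrime = IRanges::IRanges(20, 27),
                       rPrime = IRanges::IRanges(1, 7))
    expect_error(AttCSite("bad", strrep("ACGT", 20), boxes = b),
                 "within the sequence")
})

test_that("BoxAnnotation enforces 7-bp R boxes, equal L widths and ordering", {
    expect_error(boxAnnotation(rDPrime = IRanges::IRanges(50, 55),
                               lDPrime = IRanges::IRanges(35, 42),
                               lPrime = IRanges::IRanges(12, 19),
                               rPrime = IRanges::IRanges(1, 7)),
                 "7 bp")
    expect_error(boxAnnotation(rDPrime = IRanges::IRanges(50, 56),
                               lDPrime = IRanges::IRanges(35, 42),
                               lPrime = IRanges::IRanges(12, 18),
                               rPrime = IRanges::IRanges(1, 7)),
                 "equal width")
    expect_error(boxAnnotation(rDPrime = IRanges::IRanges(1, 7),
                               lDPrime = IRanges::IRanges(12, 19),
                               lPrime = IRanges::IRanges(35, 42),
                               rPrime = IRanges::IRanges(50, 56)),
                 "ordered")
})

test_that("locateBoxes recovers planted boxes exactly and reports 7-bp R boxes", {
    for (seed in c(2, 7, 19, 33)) {
        g <- generateAttc(attcParams(stem_pairs = 15 + seed %% 4,
                                     vts_len = 4 + seed %% 9), seed = seed)
        found <- locateBoxes(topStrand(g$site))
        planted <- g$truth$boxes_top
        for (slot in c("rDPrime", "lDPrime", "lPrime", "rPrime")) {
            expect_equal(IRanges::start(slot(found, slot)),
                         IRanges::start(slot(planted, slot)),
                         info = paste("seed", seed, slot))
            expect_equal(IRanges::end(slot(found, slot)),
                         IRanges::end(slot(planted, slot)),
                         info = paste("seed", seed, slot))
        }
        expect_equal(IRanges::width(slot(found, "rDPrime")), 7L)
        expect_equal(IRanges::width(slot(found, "rPrime")), 7L)
    }
})

test_that("locateBoxes refuses anchorless and too-short input", {
    expect_error(locateBoxes(strrep("A", 80)), "unannotatable")
    expect_error(locateBoxes("ACGTACGT"), "too short")
})

test_that("recombinogenic constraints contain |L| + 4 Watson-Crick pairs", {
    g8 <- generateAttc(attcParams(stem_pairs = 8, vts_len = 20), seed = 4)
    cs <- recombinogenicConstraints(g8$site)
    expect_equal(length(cs), 8L + 4L)
    # degenerate site with empty L boxes: only the R-box anchor remains
    gr <- generateAttc(attcParams(stem_pairs = 12), seed = 5)
    bx <- boxes(gr$site)
    L <- length(topStrand(gr$site))
    shrunk <- boxAnnotation(
        rDPrime = bx@rDPrime,
        lDPrime = IRanges::IRanges(IRanges::start(bx@lDPrime) +
                                       IRanges::width(bx@lDPrime), width = 0),
        lPrime = IRanges::IRanges(IRanges::start(bx@lPrime), width = 0),
        rPrime = bx@rPrime)
    site0 <- gr$site
    boxes(site0) <- shrunk
    expect_equal(length(recombinogenicConstraints(site0)), 4L)
    # all forced pairs are complementary under the planted sequence
    bs <- strsplit(bottomStrand(as.character(topStrand(g8$site))), "")[[1]]
    p <- forcedPairs(cs)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    expect_true(all(unname(comp[bs[p[, 1]]]) == bs[p[, 2]]))
})

test_that("constraint coordinates round-trip between strands", {
    g <- toySite(seed = 21)
    L <- length(topStrand(g$site))
    cs <- recombinogenicConstraints(g$site, "bottom")
    back <- flipConstraintStrand(flipConstraintStrand(cs, L), L)
    expect_identical(forcedPairs(back), forcedPairs(cs))
    expect_identical(strandLabel(back), "bottom")
    expect_identical(strandLabel(flipConstraintStrand(cs, L)), "top")
})

test_that("a forced pair between non-complementary bases is rejected", {
    g <- toySite(seed = 8)
    site <- g$site
    # complement one L' base: the forced pair becomes a same-base pair,
    # which neither Watson-Crick nor wobble rules accept
    top <- strsplit(as.character(topStrand(site)), "")[[1]]
    i <- IRanges::start(boxes(site)@lPrime) + 2L
    top[i] <- c(A = "T", C = "G", G = "C", T = "A")[top[i]]
    site2 <- suppressWarnings(AttCSite("mut", paste(top, collapse = ""),
                                       boxes = boxes(site)))
    expect_error(recombinogenicConstraints(site2), "non-complementary")
})

test_that("explicit box annotation TSV overrides the heuristic", {
    g <- toySite(seed = 31)
    bx <- boxes(g$site)
    tmp <- withr::local_tempfile(fileext = ".tsv")
    rows <- data.frame(
        site_id = siteId(g$site),
        box = c("r_dprime", "l_dprime", "l_prime", "r_prime"),
        start = c(IRanges::start(bx@rDPrime), IRanges::start(bx@lDPrime),
                  IRanges::start(bx@lPrime), IRanges::start(bx@rPrime)),
        end = c(IRanges::end(bx@rDPrime), IRanges::end(bx@lDPrime),
                IRanges::end(bx@lPrime), IRanges::end(bx@rPrime)))
    write.table(rows, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
    ann <- readBoxAnnotations(tmp)
    expect_named(ann, siteId(g$site))
    expect_equal(IRanges::start(ann[[1]]@lPrime),
                 IRanges::start(bx@lPrime))
})
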